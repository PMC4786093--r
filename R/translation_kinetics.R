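# tRNA-abundance model of translation time: the time to decode a codon is
# taken as inversely proportional to the summed cellular concentration of
# the tRNA species that recognize it.

#' Build a tRNA abundance table
#'
#' @param x data.frame with columns `trna_id`, `concentration_uM` (> 0) and
#'   `codons` (comma-separated codons recognized by the species; DNA or RNA).
#'   Wobble/modification rules are data, not code: the recognition sets in
#'   the table define the codon -> tRNA pooling and may be overridden freely.
#' @return a `trna_table` with attribute `codon_pool`: named numeric vector
#'   codon (RNA) -> summed concentration of all recognizing species.
#' @export
trna_table <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("trna_id", "concentration_uM", "codons") %in% names(x)))
  if (any(!is.finite(x$concentration_uM)) || any(x$concentration_uM <= 0))
    stop("concentrations must be positive and finite")
  rec <- lapply(strsplit(as.character(x$codons), ","), function(s) {
    s <- as_rna(toupper(trimws(s)))
    if (any(!s %in% as_rna(.sense_codons())))
      stop("unknown codon in recognition set: ",
           paste(s[!s %in% as_rna(.sense_codons())], collapse = ", "))
    s
  })
  pool <- tapply(rep(x$concentration_uM, lengths(rec)), unlist(rec), sum)
  structure(x, class = c("trna_table", "data.frame"),
            codon_pool = setNames(as.numeric(pool), names(pool)))
}

#' Read a tRNA abundance table from TSV
#'
#' @param path TSV with columns `trna_id`, `concentration_uM`, `codons`.
#' @return a [trna_table()].
#' @export
read_trna_table <- function(path) {
  trna_table(read_tsv(path))
}

#' Bundled synthetic tRNA abundance fixture
#'
#' A stand-in table with the schema of published E. coli K12 tRNA
#' concentration measurements (species, concentration in micromolar,
#' recognized codons under standard bacterial wobble rules). The values are
#' synthetic: plausible in rank and magnitude, not measured data.
#'
#' @return a `trna_table`.
#' @export
example_trna_table <- function() {
  read_trna_table(system.file("extdata", "trna_abundance_synthetic.tsv",
                              package = "codonfit", mustWork = TRUE))
}

#' Pooled tRNA concentration recognizing a codon
#'
#' @param table a [trna_table()].
#' @param codon a sense codon (DNA or RNA).
#' @return summed concentration (micromolar) over all recognizing species.
#' @export
codon_pool <- function(table, codon) {
  stopifnot(inherits(table, "trna_table"))
  pool <- attr(table, "codon_pool")
  key <- as_rna(toupper(codon))
  miss <- setdiff(key, names(pool))
  if (length(miss) > 0L)
    stop("no tRNA species recognizes codon: ", paste(miss, collapse = ", "))
  unname(pool[key])
}

#' Increase in translation time for a synonymous codon
#'
#' `delta_t = 1 / n_syn - 1 / n_wt`, where `n` is the pooled concentration
#' of tRNA species recognizing each codon. Units are reciprocal micromolar;
#' only the relative scale is meaningful (the quantity is used in
#' correlations, not as an absolute time). The value is negative when the
#' synonymous codon is read by a more abundant tRNA pool than the wild-type
#' codon.
#'
#' @param table a [trna_table()].
#' @param codon_syn,codon_wt codons (DNA or RNA).
#' @return a `translation_time_delta`: list with `codon_syn`, `codon_wt`,
#'   `n_syn`, `n_wt`, `delta_t`.
#' @examples
#' tab <- trna_table(data.frame(trna_id = c("t1", "t2"),
#'                              concentration_uM = c(2, 4),
#'                              codons = c("CUA", "CUG")))
#' delta_t_trans(tab, "CUA", "CUG")$delta_t  # 1/2 - 1/4 = 0.25
#' @export
delta_t_trans <- function(table, codon_syn, codon_wt) {
  n_syn <- codon_pool(table, codon_syn)
  n_wt <- codon_pool(table, codon_wt)
  if (n_syn <= 0 || n_wt <= 0) stop("zero tRNA pool: delta_t undefined")
  structure(list(codon_syn = as_rna(toupper(codon_syn)),
                 codon_wt = as_rna(toupper(codon_wt)),
                 n_syn = n_syn, n_wt = n_wt,
                 delta_t = 1 / n_syn - 1 / n_wt),
            class = "translation_time_delta")
}

#' @export
print.translation_time_delta <- function(x, ...) {
  cat(sprintf("<delta_t> %s vs %s: %.4g (1/uM)\n",
              x$codon_syn, x$codon_wt, x$delta_t))
  invisible(x)
}
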