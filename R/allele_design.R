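# Synonymous allele design: systematic codon replacement behind a protected
# 5' prefix, with optional source-codon filtering, region restriction and
# multi-amino-acid combination.

#' Specify a synonymous redesign
#'
#' @param replacements named character vector: amino acid (one- or
#'   three-letter) -> target synonymous codon (DNA or RNA), e.g.
#'   `c(Leu = "UUA")` or `c(Leu = "UUA", Pro = "CCA")`.
#' @param source_filter optional named character vector, amino acid ->
#'   source codon: only that codon is replaced (e.g. only CGU -> CGG).
#' @param region `"full"`, `"first_half"`, `"second_half"`, or an explicit
#'   integer codon interval `c(start, end)` (1-based, inclusive).
#' @param protected_prefix integer, number of leading codons never edited
#'   (default 40, shielding the translation-initiation region).
#' @return a `design_spec` object.
#' @examples
#' design_spec(c(Leu = "UUA"))
#' design_spec(c(Arg = "CGG"), source_filter = c(Arg = "CGU"))
#' @export
design_spec <- function(replacements, source_filter = NULL,
                        region = "full", protected_prefix = 40L) {
  stopifnot(is.character(replacements), length(replacements) >= 1L,
            !is.null(names(replacements)))
  aa <- aa_one_letter(names(replacements))
  target <- as_dna(replacements)
  gc <- .genetic_code()
  if (any(gc[target] != aa))
    stop("target codon not synonymous with its amino acid: ",
         paste(as_rna(target[gc[target] != aa]), collapse = ", "))
  names(target) <- aa
  src <- NULL
  if (!is.null(source_filter)) {
    saa <- aa_one_letter(names(source_filter))
    src <- as_dna(source_filter)
    if (any(gc[src] != saa))
      stop("source_filter codon does not encode its amino acid")
    names(src) <- saa
    if (!all(saa %in% aa)) stop("source_filter names must be a subset of replacements")
  }
  if (is.numeric(region)) {
    stopifnot(length(region) == 2L, region[1] >= 1L, region[2] >= region[1])
    region <- as.integer(region)
  } else {
    region <- match.arg(region, c("full", "first_half", "second_half"))
  }
  protected_prefix <- as.integer(protected_prefix)
  stopifnot(protected_prefix >= 0L)
  structure(list(replacements = target, source_filter = src,
                 region = region, protected_prefix = protected_prefix),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>",
      paste(sprintf("%s->%s", names(x$replacements), as_rna(x$replacements)),
            collapse = ", "),
      sprintf("| region: %s | prefix: %d\n",
              paste(x$region, collapse = "-"), x$protected_prefix))
  invisible(x)
}

# editable codon indices of `parent` under `spec` (excludes prefix and a
# terminal stop); `boundary` is the last codon index of the first half
.editable_range <- function(parent, spec, boundary = NULL) {
  nc <- n_codons(parent)
  last <- nc
  if (.genetic_code()[codons(parent)[nc]] == "*") last <- nc - 1L
  first <- spec$protected_prefix + 1L
  if (first > last) stop("protected prefix spans the whole gene")
  if (is.numeric(spec$region)) {
    if (spec$region[2] > last || spec$region[1] < 1L)
      stop("region outside gene")
    return(max(first, spec$region[1]):spec$region[2])
  }
  if (is.null(boundary)) boundary <- first + (last - first) %/% 2L
  switch(spec$region,
         full = first:last,
         first_half = first:boundary,
         second_half = (boundary + 1L):last)
}

#' Design a synonymous allele
#'
#' Replaces every codon in the editable region (beyond the protected prefix)
#' that encodes a targeted amino acid — and matches the source filter, if one
#' is set — by the target synonymous codon. The protein sequence is preserved
#' by construction and re-verified. The stop codon is never edited.
#'
#' @param parent a `coding_sequence`.
#' @param spec a [design_spec()].
#' @param boundary optional codon index of the first/second-half split
#'   (default: midpoint of the editable range).
#' @return a `synonymous_allele`: list with `seq` (the new
#'   `coding_sequence`), `substitutions` (data.frame `codon_index`, `from`,
#'   `to`, RNA alphabet) and `N` (substitution count).
#' @examples
#' p <- coding_sequence("p", paste0(strrep("AAA", 40), "CTGCCGAAA", "TAA"))
#' a <- design_allele(p, design_spec(c(Leu = "UUA")))
#' a$substitutions
#' @export
design_allele <- function(parent, spec, boundary = NULL) {
  stopifnot(inherits(parent, "coding_sequence"), inherits(spec, "design_spec"))
  cod <- codons(parent)
  gc <- .genetic_code()
  idx <- .editable_range(parent, spec, boundary)
  aa <- gc[cod[idx]]
  hit <- aa %in% names(spec$replacements)
  if (!is.null(spec$source_filter)) {
    filt <- names(spec$source_filter)
    f <- aa %in% filt
    hit[f] <- hit[f] & cod[idx][f] == spec$source_filter[aa[f]]
  }
  new_cod <- cod
  tgt <- spec$replacements[aa[hit]]
  changed <- idx[hit][tgt != cod[idx][hit]]
  new_cod[idx[hit]] <- tgt
  subs <- data.frame(codon_index = changed,
                     from = as_rna(cod[changed]),
                     to = as_rna(new_cod[changed]),
                     stringsAsFactors = FALSE)
  allele <- coding_sequence(paste0(parent$id, "_syn"),
                            paste(new_cod, collapse = ""))
  if (!identical(translate_cds(allele), translate_cds(parent)))
    stop("internal error: designed allele changes the protein")  # defensive
  structure(list(seq = allele, substitutions = subs, N = nrow(subs),
                 parent_id = parent$id),
            class = "synonymous_allele")
}

#' @export
print.synonymous_allele <- function(x, ...) {
  cat(sprintf("<synonymous_allele> %s: N = %d substitutions\n", x$seq$id, x$N))
  invisible(x)
}

#' Split a design into first-half and second-half specs
#'
#' Produces two specs whose regions partition the editable codon range, so
#' that the substitution counts of the two half-designs always sum to the
#' substitution count of the full design.
#'
#' @inheritParams design_allele
#' @param boundary last codon index of the first half (default: midpoint of
#'   the editable range). The split of targeted codons between halves depends
#'   on the actual sequence, so N per half is reported from the diff, never
#'   assumed.
#' @return list with elements `first` and `second`, both `design_spec`s with
#'   explicit interval regions.
#' @export
split_regions <- function(parent, spec, boundary = NULL) {
  stopifnot(inherits(parent, "coding_sequence"), inherits(spec, "design_spec"))
  idx <- .editable_range(parent, spec, boundary = NULL)
  first <- idx[1L]; last <- idx[length(idx)]
  if (last - first < 1L) stop("fewer than 2 editable codons")
  if (is.null(boundary)) boundary <- first + (last - first) %/% 2L
  boundary <- as.integer(boundary)
  if (boundary < first || boundary >= last)
    stop("boundary must lie inside the editable range")
  mk <- function(rg) {
    s <- spec; s$region <- rg; s
  }
  list(first = mk(c(first, boundary)), second = mk(c(boundary + 1L, last)))
}

#' Codon-level differences between two equal-length coding sequences
#'
#' @param a,b `coding_sequence` objects of equal length.
#' @return data.frame with columns `codon_index` (1-based), `from` (codon in
#'   `b`), `to` (codon in `a`), RNA alphabet. `diff_alleles(designed$seq,
#'   parent)` reproduces `designed$substitutions`.
#' @export
diff_alleles <- function(a, b) {
  stopifnot(inherits(a, "coding_sequence"), inherits(b, "coding_sequence"))
  if (nchar(a$seq) != nchar(b$seq)) stop("sequences differ in length")
  ca <- codons(a); cb <- codons(b)
  i <- which(ca != cb)
  data.frame(codon_index = i, from = as_rna(cb[i]), to = as_rna(ca[i]),
             stringsAsFactors = FALSE)
}
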