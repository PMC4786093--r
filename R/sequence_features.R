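# Anti-Shine-Dalgarno hexamer scanning and ingestion of precomputed mRNA
# folding free-energy differences. Internal Shine-Dalgarno-like hexamers can
# pair with the 3' tail of 16S rRNA and stall elongating ribosomes; alleles
# are scanned whole, in all three frames (every nucleotide offset).

# Nearest-neighbor RNA:RNA stack free energies (kcal/mol, 37 C), Turner-style
# values for Watson-Crick stacks plus representative G:U wobble stacks.
# Keys are 5'->3' top-strand dinucleotides paired to the antiparallel
# complement, canonicalized so XY/X'Y' and its rotation share one entry.
.rna_nn_stacks <- c(
  "AA" = -0.93, "AU" = -1.10, "UA" = -1.33, "CU" = -2.08, "CA" = -2.11,
  "GU" = -2.24, "GA" = -2.35, "CG" = -2.36, "GG" = -3.26, "GC" = -3.42,
  "UU" = -0.93, "UG" = -2.11, "AG" = -2.08, "AC" = -2.24, "UC" = -2.35,
  "CC" = -3.26)
.nn_init <- 4.09        # duplex initiation
.nn_term_au <- 0.45     # per terminal A-U (or G-U) pair
.gu_penalty <- 1.3      # softening applied per G:U pair in a helix

.base_pairs <- function(a, b) {
  # returns TRUE where a (mRNA) can pair with b (anti-SD), WC or G:U
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

# Best (minimum) hybridization energy of a 6-mer against an anti-SD tail:
# slide all antiparallel alignments, score every contiguous paired run of
# length >= 2 by summed nearest-neighbor stacks + initiation + terminal/GU
# penalties, take the minimum; 0 if no alignment yields a stable duplex.
.duplex_energy_one <- function(hex, asd_rev) {
  h <- strsplit(hex, "")[[1]]
  m <- length(asd_rev)
  best <- 0
  for (off in (-5L):(m - 1L)) {
    i <- pmax(1L, 1L - off):pmin(6L, m - off)
    j <- i + off
    p <- .base_pairs(h[i], asd_rev[j])
    if (!any(p)) next
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      ii <- i[starts[k]:ends[k]]
      jj <- ii + off
      stacks <- .rna_nn_stacks[paste0(h[ii[-length(ii)]], h[ii[-1L]])]
      gu <- (h[ii] == "G" & asd_rev[jj] == "U") | (h[ii] == "U" & asd_rev[jj] == "G")
      au_term <- sum((h[ii[c(1L, length(ii))]] %in% c("A", "U")) | gu[c(1L, length(gu))])
      e <- sum(stacks) + .nn_init + .nn_term_au * au_term + .gu_penalty * sum(gu)
      if (e < best) best <- e
    }
  }
  best
}

.model_cache <- new.env(parent = emptyenv())

#' Hexamer affinity model against the anti-Shine-Dalgarno sequence
#'
#' Holds a complete energy map hexamer -> hybridization free energy
#' (kcal/mol) against the anti-SD tail of 16S rRNA. By default the map is
#' generated once per anti-SD sequence with a nearest-neighbor RNA:RNA
#' duplex calculation (Watson-Crick and G:U stacks, duplex initiation and
#' terminal penalties) and cached; it is a deterministic synthetic stand-in
#' for experimentally parameterized hybridization models, adequate because
#' downstream analyses use only the ranking of strongly pairing windows.
#' A user-supplied map (e.g. from an external folding tool) overrides it.
#'
#' @param anti_sd anti-SD sequence, 5'->3' RNA (default `"CACCUCCUUA"`, the
#'   3'-terminal tail of bacterial 16S rRNA).
#' @param energies optional named numeric vector hexamer -> kcal/mol. Must
#'   cover every hexamer that will be looked up; scanning fails loudly on a
#'   missing window.
#' @return a `hexamer_model`: list with `anti_sd` and `energy` (named vector
#'   over all 4096 RNA hexamers when generated internally).
#' @export
hexamer_affinity_model <- function(anti_sd = "CACCUCCUUA", energies = NULL) {
  anti_sd <- as_rna(toupper(anti_sd))
  if (!grepl("^[ACGU]+$", anti_sd)) stop("anti_sd must be an RNA string")
  if (is.null(energies)) {
    key <- anti_sd
    if (is.null(.model_cache[[key]])) {
      nts <- c("A", "C", "G", "U")
      hex <- do.call(paste0, expand.grid(nts, nts, nts, nts, nts, nts,
                                         stringsAsFactors = FALSE))
      asd_rev <- rev(strsplit(anti_sd, "")[[1]])
      e <- vapply(hex, .duplex_energy_one, numeric(1L), asd_rev = asd_rev)
      .model_cache[[key]] <- setNames(e, hex)
    }
    energies <- .model_cache[[key]]
  } else {
    if (is.null(names(energies)) || !all(is.finite(energies)))
      stop("energies must be a finite named vector")
    names(energies) <- as_rna(toupper(names(energies)))
  }
  structure(list(anti_sd = anti_sd, energy = energies), class = "hexamer_model")
}

#' Scan a sequence for hexamers with strong anti-SD affinity
#'
#' Slides a 6-nt window at every nucleotide offset (all three reading
#' frames) and counts windows with hybridization energy strictly below each
#' threshold.
#'
#' @param seq a `coding_sequence` or nucleotide string (length >= 6).
#' @param model a [hexamer_affinity_model()].
#' @param thresholds numeric vector of kcal/mol cutoffs (default `c(-4, -6)`).
#' @return an `anti_sd_scan`: list with `counts` (named by threshold) and
#'   `positions` (data.frame `offset`, `hexamer`, `dG` for windows below the
#'   weakest threshold).
#' @examples
#' m <- hexamer_affinity_model()
#' scan_anti_sd("AUGGAGGUAAUAUGA", m)$counts
#' @export
scan_anti_sd <- function(seq, model, thresholds = c(-4, -6)) {
  stopifnot(inherits(model, "hexamer_model"), length(thresholds) >= 1L)
  s <- as_rna(if (inherits(seq, "coding_sequence")) seq$seq else toupper(seq))
  L <- nchar(s)
  if (L < 6L) stop("sequence shorter than 6 nt")
  win <- substring(s, 1:(L - 5L), 6:L)
  dg <- model$energy[win]
  if (anyNA(dg))
    stop("hexamer absent from energy model: ", win[which(is.na(dg))[1L]])
  counts <- vapply(thresholds, function(th) sum(dg < th), integer(1L))
  names(counts) <- as.character(thresholds)
  keep <- dg < max(thresholds)
  structure(list(counts = counts,
                 positions = data.frame(offset = which(keep),
                                        hexamer = win[keep],
                                        dG = unname(dg[keep]),
                                        stringsAsFactors = FALSE)),
            class = "anti_sd_scan")
}

#' @export
print.anti_sd_scan <- function(x, ...) {
  cat("<anti_sd_scan> windows below threshold:",
      paste(sprintf("%s kcal/mol: %d", names(x$counts), x$counts),
            collapse = "; "), "\n")
  invisible(x)
}

#' Load precomputed mRNA folding free-energy differences
#'
#' Folding free energies are consumed, not computed: the table gives, per
#' allele, the change in predicted mRNA free energy relative to the wild
#' type (kcal/mol, as supplied by an external folding prediction). Signed
#' values are accepted as-is.
#'
#' @param x data.frame with columns `allele` and `ddg`, or a path to such a
#'   TSV.
#' @return data.frame of validated records; rows with a missing allele id
#'   are dropped with a warning, duplicated ids keep the last row with a
#'   warning.
#' @export
load_ddg <- function(x) {
  if (is.character(x)) x <- read_tsv(x)
  stopifnot(is.data.frame(x), all(c("allele", "ddg") %in% names(x)))
  bad <- is.na(x$allele) | x$allele == ""
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing allele id dropped")
    x <- x[!bad, , drop = FALSE]
  }
  x$ddg <- as.numeric(x$ddg)
  dup <- duplicated(x$allele, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate allele id(s), keeping last: ",
            paste(unique(x$allele[dup]), collapse = ", "))
    x <- x[!dup, , drop = FALSE]
  }
  rownames(x) <- NULL
  x[, c("allele", "ddg")]
}
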