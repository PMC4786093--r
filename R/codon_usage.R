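# Codon counting, RSCU and relative adaptiveness (wa) from a reference set
# of highly expressed genes.

# data.frame of sense codons with their amino acid and synonymous family size
.codon_info <- function() {
  gc <- .genetic_code()
  sense <- gc[gc != "*"]
  fam <- table(sense)
  data.frame(codon = names(sense),
             amino_acid = unname(sense),
             family_size = as.integer(fam[sense]),
             stringsAsFactors = FALSE)
}

#' Count codons in a gene set with N-terminal exclusion
#'
#' Tallies codons over a set of coding sequences, skipping the first
#' `exclude_first` codons of every gene. Highly expressed bacterial genes
#' carry a distinct codon bias at the N-terminus (translation-initiation
#' ramp), so usage statistics for elongation-level bias conventionally drop
#' the leading codons; the default drops forty. Stop codons are tallied
#' separately and excluded from synonymous families.
#'
#' @param genes a `coding_sequence` or list of them.
#' @param exclude_first integer >= 0, leading codons skipped per gene.
#' @return a `codon_counts` data.frame with columns `codon` (RNA alphabet),
#'   `amino_acid`, `family_size`, `count`, and attributes `excluded_prefix`
#'   and `stop_counts`.
#' @examples
#' g <- coding_sequence("g", "ATGTTATAA")
#' count_codons(g, exclude_first = 0)
#' @export
count_codons <- function(genes, exclude_first = 40L) {
  if (inherits(genes, "coding_sequence")) genes <- list(genes)
  stopifnot(length(genes) >= 1L, all(vapply(genes, inherits, TRUE, "coding_sequence")))
  exclude_first <- as.integer(exclude_first)
  if (is.na(exclude_first) || exclude_first < 0L)
    stop("exclude_first must be a non-negative integer")
  all_cod <- unlist(lapply(genes, function(g) {
    cod <- codons(g)
    if (length(cod) < exclude_first + 1L)
      stop(sprintf("gene '%s' has %d codons; cannot exclude the first %d",
                   g$id, length(cod), exclude_first))
    cod[(exclude_first + 1L):length(cod)]
  }))
  info <- .codon_info()
  tab <- table(factor(all_cod, levels = c(info$codon, .stop_codons())))
  out <- info
  out$count <- as.integer(tab[info$codon])
  out$codon <- as_rna(out$codon)
  structure(out,
            class = c("codon_counts", "data.frame"),
            excluded_prefix = exclude_first,
            stop_counts = as.integer(tab[.stop_codons()]))
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if all
#' members of its synonymous family were used equally:
#' `count * family_size / family_total`. A family with zero total usage gets
#' `NA` for all members.
#'
#' @param counts a `codon_counts` table from [count_codons()].
#' @return the table with an added `rscu` column (class `rscu_table`).
#' @export
compute_rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  fam_tot <- tapply(counts$count, counts$amino_acid, sum)[counts$amino_acid]
  rscu <- ifelse(fam_tot > 0, counts$count * counts$family_size / fam_tot, NA_real_)
  counts$rscu <- as.numeric(rscu)
  class(counts) <- unique(c("rscu_table", class(counts)))
  counts
}

# resolve per-family reference codons (RNA alphabet), given an rscu table
.resolve_reference <- function(tbl, reference) {
  fams <- split(seq_len(nrow(tbl)), tbl$amino_acid)
  if (identical(reference, "max")) {
    vapply(fams, function(i) {
      r <- tbl$rscu[i]
      if (all(is.na(r))) return(NA_character_)
      # highest RSCU; ties broken by codon string for determinism
      cand <- tbl$codon[i][which(r == max(r, na.rm = TRUE))]
      sort(cand)[1L]
    }, character(1L))
  } else {
    ref <- as_rna(toupper(reference))
    aa <- .genetic_code()[as_dna(ref)]
    if (anyNA(aa) || any(aa == "*"))
      stop("reference contains a non-sense codon")
    names(ref) <- aa
    full <- vapply(names(fams), function(a) {
      if (a %in% names(ref)) unname(ref[a]) else {
        i <- fams[[a]]
        r <- tbl$rscu[i]
        if (all(is.na(r))) NA_character_
        else sort(tbl$codon[i][which(r == max(r, na.rm = TRUE))])[1L]
      }
    }, character(1L))
    full
  }
}

#' Relative adaptiveness of codons
#'
#' The relative adaptiveness of a codon is its RSCU divided by the RSCU of
#' its family's reference (wild-type optimal) codon, `wa = RSCU_syn /
#' RSCU_wt`, so that the optimal codon has `wa = 1` and `log_wa = 0`.
#' `log_wa` is the base-10 logarithm, the linear-scale proxy for selection on
#' codon choice.
#'
#' @param rscu_table an `rscu_table` from [compute_rscu()].
#' @param reference `"max"` (default: the maximum-RSCU codon of each family,
#'   which for highly expressed gene sets is the wild-type optimal codon), or
#'   a character vector of explicit reference codons, one per family to
#'   override (families not mentioned fall back to the maximum).
#' @return the table with added columns `wa`, `log_wa` and `is_reference`
#'   (class `adaptiveness_table`).
#' @examples
#' genes <- replicate(3, coding_sequence("g", strrep("CTGAAA", 30)), simplify = FALSE)
#' wa <- compute_wa(compute_rscu(count_codons(genes, 0)))
#' subset(wa, amino_acid == "L")
#' @export
compute_wa <- function(rscu_table, reference = "max") {
  stopifnot(inherits(rscu_table, "rscu_table"))
  tbl <- rscu_table
  ref <- .resolve_reference(tbl, reference)
  ref_rscu <- tbl$rscu[match(ref[tbl$amino_acid], tbl$codon)]
  if (any(!is.na(ref_rscu) & ref_rscu == 0)) {
    bad <- unique(tbl$amino_acid[!is.na(ref_rscu) & ref_rscu == 0])
    stop("reference codon has zero RSCU for family: ", paste(bad, collapse = ", "))
  }
  tbl$wa <- tbl$rscu / ref_rscu
  tbl$wa[tbl$codon == ref[tbl$amino_acid]] <- 1  # exact for the reference codon
  tbl$log_wa <- log10(tbl$wa)
  tbl$is_reference <- tbl$codon == ref[tbl$amino_acid]
  class(tbl) <- unique(c("adaptiveness_table", class(tbl)))
  tbl
}

#' One-step relative adaptiveness from a reference gene set
#'
#' Convenience wrapper: [count_codons()] with N-terminal exclusion, then
#' [compute_rscu()] and [compute_wa()].
#'
#' @inheritParams count_codons
#' @inheritParams compute_wa
#' @return an `adaptiveness_table`.
#' @export
relative_adaptiveness <- function(genes, exclude_first = 40L, reference = "max") {
  compute_wa(compute_rscu(count_codons(genes, exclude_first)), reference)
}

#' Look up log10 relative adaptiveness of codons
#'
#' @param table an `adaptiveness_table`.
#' @param codon character vector of codons (DNA or RNA).
#' @return numeric vector of `log_wa` values.
#' @export
log_wa <- function(table, codon) {
  stopifnot(inherits(table, "adaptiveness_table"))
  i <- match(as_rna(toupper(codon)), table$codon)
  if (anyNA(i)) stop("codon not in table: ", paste(codon[is.na(i)], collapse = ", "))
  table$log_wa[i]
}
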