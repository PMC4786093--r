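# Relative mRNA quantification and half-life estimation from rifampicin
# run-out qPCR series (delta-delta-Ct with an assumed amplification
# efficiency of 2; multiple dilutions averaged after dilution correction).

.collapse_ct <- function(ct, sample, gene, timepoint, efficiency = 2) {
  rows <- ct$sample == sample & ct$gene == gene & ct$timepoint_min == timepoint
  if (!any(rows)) return(NA_real_)
  dil <- if ("dilution" %in% names(ct)) as.numeric(ct$dilution[rows]) else 1
  # a d-fold diluted template crosses threshold log_eff(d) cycles later
  mean(as.numeric(ct$ct[rows]) - log(dil, base = efficiency))
}

#' Relative mRNA abundance by delta-delta-Ct
#'
#' Target Ct is referenced against the mean of the reference genes at the
#' same timepoint (delta-Ct), then against the same quantity in the
#' calibrator sample (delta-delta-Ct); the relative quantity is
#' `efficiency^(-ddCt)`. Technical dilutions (1, 1:10, 1:100) are averaged
#' after dilution correction.
#'
#' @param ct data.frame with columns `sample`, `gene`, `timepoint_min`,
#'   `ct` and optionally `dilution` (fold, e.g. 1, 10, 100).
#' @param target target gene name (e.g. `"tuf"`).
#' @param references character vector of reference gene names.
#' @param sample sample (allele) to quantify.
#' @param calibrator sample the quantity is expressed relative to.
#' @param timepoint timepoint in minutes (default 0).
#' @param efficiency assumed amplification efficiency (default 2).
#' @return relative quantity (calibrator = 1).
#' @export
relative_abundance <- function(ct, target, references, sample, calibrator,
                               timepoint = 0, efficiency = 2) {
  stopifnot(is.data.frame(ct),
            all(c("sample", "gene", "timepoint_min", "ct") %in% names(ct)),
            length(references) >= 1L, efficiency > 1)
  dct <- function(smp) {
    tar <- .collapse_ct(ct, smp, target, timepoint, efficiency)
    refs <- vapply(references, .collapse_ct, numeric(1L),
                   ct = ct, sample = smp, timepoint = timepoint,
                   efficiency = efficiency)
    if (is.na(tar) || anyNA(refs))
      stop("missing measurement for sample '", smp, "' at t = ", timepoint,
           " (target or reference)")
    tar - mean(refs)
  }
  efficiency^(-(dct(sample) - dct(calibrator)))
}

#' mRNA half-life from a rifampicin run-out series
#'
#' For each timepoint the target quantity relative to time zero is computed
#' by delta-delta-Ct against a stable reference gene; the log2 relative
#' quantity is regressed on time and the half-life is `-1 / slope` minutes.
#' A flat or increasing series is flagged as not estimable.
#'
#' @inheritParams relative_abundance
#' @param reference a single stable reference gene (e.g. tmRNA).
#' @param timepoints timepoints to use (default: all present for the sample).
#' @return list with `half_life_min`, `slope`, `r_squared`, `estimable`,
#'   and the per-timepoint `relative` quantities.
#' @export
half_life <- function(ct, target, reference, sample,
                      timepoints = NULL, efficiency = 2) {
  stopifnot(is.data.frame(ct), length(reference) == 1L)
  if (is.null(timepoints))
    timepoints <- sort(unique(ct$timepoint_min[ct$sample == sample]))
  if (length(timepoints) < 3L) stop("need at least 3 timepoints")
  # quantity at each timepoint relative to the first (delta-delta-Ct)
  dct <- vapply(timepoints, function(tp)
    .collapse_ct(ct, sample, target, tp, efficiency) -
      .collapse_ct(ct, sample, reference, tp, efficiency), numeric(1L))
  if (anyNA(dct)) stop("missing measurement in run-out series")
  rel <- efficiency^(-(dct - dct[1L]))
  fit <- stats::lm(log2(rel) ~ timepoints)
  slope <- unname(stats::coef(fit)[2L])
  estimable <- is.finite(slope) && slope < 0
  list(half_life_min = if (estimable) -1 / slope else NA_real_,
       slope = slope,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       estimable = estimable,
       relative = stats::setNames(rel, timepoints))
}
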