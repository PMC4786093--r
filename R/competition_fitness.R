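# Selection-coefficient estimation from serial-transfer competition
# trajectories, and the filtering / normalization / comparison chain that
# turns replicate slopes into a per-allele selective disadvantage.

#' Estimate a selection coefficient from one competition trajectory
#'
#' The selection coefficient is the per-generation slope of the natural-log
#' ratio of focal to reference strain. The default estimator is the ordinary
#' least-squares slope of `ln(ratio)` on generation over all time points; the
#' `"endpoints"` option uses only the first and last observations,
#' `ln(R_final / R_0) / (g_final - g_0)`.
#'
#' @param trajectory data.frame with columns `generation` (strictly
#'   increasing) and `ratio` (focal/reference, > 0), one replicate culture.
#' @param method `"ols"` (default) or `"endpoints"`.
#' @return numeric selection coefficient per generation (negative when the
#'   focal strain loses).
#' @examples
#' tr <- data.frame(generation = c(0, 10, 20, 30),
#'                  ratio = exp(-0.003 * c(0, 10, 20, 30)))
#' estimate_s(tr)
#' @export
estimate_s <- function(trajectory, method = c("ols", "endpoints")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(trajectory),
            all(c("generation", "ratio") %in% names(trajectory)))
  g <- as.numeric(trajectory$generation)
  r <- as.numeric(trajectory$ratio)
  if (length(g) < 2L) stop("need at least 2 observations")
  if (any(diff(g) <= 0)) stop("generations must be strictly increasing")
  if (any(!is.finite(r)) || any(r <= 0)) stop("ratios must be positive")
  y <- log(r)
  if (method == "endpoints")
    return((y[length(y)] - y[1L]) / (g[length(g)] - g[1L]))
  sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
}

#' Estimate selection coefficients for every replicate in a trajectory table
#'
#' @param traj data.frame with columns `strain`, `dye`, `replicate`,
#'   `generation` and either `ratio` or raw marker counts `count_focal` /
#'   `count_reference` (converted to a ratio).
#' @inheritParams estimate_s
#' @return data.frame with columns `strain`, `dye`, `replicate`, `s`.
#' @export
estimate_selection <- function(traj, method = c("ols", "endpoints")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(traj),
            all(c("strain", "dye", "replicate", "generation") %in% names(traj)))
  if (!"ratio" %in% names(traj)) {
    if (!all(c("count_focal", "count_reference") %in% names(traj)))
      stop("need a 'ratio' column or 'count_focal'/'count_reference'")
    traj$ratio <- traj$count_focal / traj$count_reference
  }
  key <- interaction(traj$strain, traj$dye, traj$replicate, drop = TRUE)
  parts <- split(traj[, c("generation", "ratio")], key)
  meta <- traj[!duplicated(key), c("strain", "dye", "replicate")]
  meta <- meta[match(names(parts), key[!duplicated(key)]), ]
  out <- data.frame(meta,
                    s = vapply(parts, estimate_s, numeric(1L), method = method),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$strain, out$dye, out$replicate), , drop = FALSE]
}

#' Median-window outlier filter for selection coefficients
#'
#' Removes estimates further than `window` from the median of the input
#' group (single pass: the median is computed once on the raw group, not
#' iteratively). The default window of 0.008 per generation reflects the
#' empirical spread of clean replicate competitions; excursions beyond it
#' indicate a secondary genetic change in that culture rather than the
#' fitness of the allele under test.
#'
#' @param s numeric vector of selection coefficients (one group).
#' @param window numeric, half-width of the acceptance window (default 0.008).
#' @return list with `kept`, `removed`, `kept_index`, `removed_index`,
#'   `median`.
#' @export
filter_outliers <- function(s, window = 0.008) {
  stopifnot(is.numeric(s), length(s) >= 1L, is.finite(window), window >= 0)
  med <- stats::median(s)
  out <- abs(s - med) > window
  list(kept = s[!out], removed = s[out],
       kept_index = which(!out), removed_index = which(out),
       median = med)
}

#' Apply the outlier filter per group of a selection-estimate table
#'
#' @param estimates data.frame from [estimate_selection()].
#' @param window see [filter_outliers()].
#' @param by columns defining a group (default `c("strain", "dye")`: the
#'   twelve replicates of one strain in one dye orientation).
#' @return the table with a logical column `kept`.
#' @export
filter_outliers_grouped <- function(estimates, window = 0.008,
                                    by = c("strain", "dye")) {
  stopifnot(is.data.frame(estimates), "s" %in% names(estimates),
            all(by %in% names(estimates)))
  key <- interaction(estimates[by], drop = TRUE)
  kept <- logical(nrow(estimates))
  for (k in levels(key)) {
    i <- which(key == k)
    kept[i] <- seq_along(i) %in% filter_outliers(estimates$s[i], window)$kept_index
  }
  estimates$kept <- kept
  estimates
}

#' Normalize selection coefficients to the wild-type control of each batch
#'
#' Each estimate is expressed relative to the mean selection coefficient of
#' the control (wild-type) strain measured in the same dye batch, so that
#' marker-specific effects cancel across dye swaps and the control group
#' mean maps to 0 within every batch.
#'
#' @param estimates data.frame with columns `strain`, `dye`, `s` (typically
#'   after [filter_outliers_grouped()]; rows with `kept == FALSE` are
#'   ignored for the control mean and dropped from the output).
#' @param control character, control strain id (default `"tufA"`).
#' @return the kept rows with an added column `s_norm`.
#' @export
normalize_to_reference <- function(estimates, control = "tufA") {
  stopifnot(is.data.frame(estimates),
            all(c("strain", "dye", "s") %in% names(estimates)))
  if (!"kept" %in% names(estimates)) estimates$kept <- TRUE
  est <- estimates[estimates$kept, , drop = FALSE]
  est$s_norm <- NA_real_
  for (d in unique(est$dye)) {
    ctrl <- est$s[est$dye == d & est$strain == control]
    if (length(ctrl) == 0L)
      stop("no control ('", control, "') measurements in dye batch '", d, "'")
    est$s_norm[est$dye == d] <- est$s[est$dye == d] - mean(ctrl)
  }
  est
}

#' Compare a test allele against the wild-type control group
#'
#' Selective disadvantage of the test allele, defined as the average
#' difference between the control and test groups of normalized selection
#' coefficients (positive when the test allele grows worse), with a
#' two-sided t-test (Welch by default) and the 95% confidence interval of
#' the mean difference.
#'
#' @param test,control numeric vectors of normalized selection coefficients
#'   (each of length >= 2).
#' @param var_equal logical; `FALSE` (default) for Welch's unequal-variance
#'   test, `TRUE` for the pooled-variance test.
#' @param conf_level confidence level for the interval (default 0.95).
#' @param allele optional label carried into the result.
#' @return a `selection_result`: list with `allele`, `disadvantage`, `ci95`,
#'   `p_value`, `n_used`, `se`, `df`, and the group summaries.
#' @export
compare_groups <- function(test, control, var_equal = FALSE,
                           conf_level = 0.95, allele = NA_character_) {
  stopifnot(is.numeric(test), is.numeric(control),
            length(test) >= 2L, length(control) >= 2L)
  d <- mean(control) - mean(test)
  tt <- tryCatch(stats::t.test(control, test, var.equal = var_equal,
                               conf.level = conf_level),
                 error = function(e) {
                   if (!grepl("essentially constant", conditionMessage(e)))
                     stop(e)
                   NULL
                 })
  if (is.null(tt)) {
    warning("groups have (essentially) zero variance; confidence interval collapsed")
    res <- list(disadvantage = d, ci95 = c(d, d),
                p_value = if (d == 0) 1 else 0,
                se = 0, df = length(test) + length(control) - 2L)
  } else {
    res <- list(disadvantage = d, ci95 = unname(tt$conf.int),
                p_value = unname(tt$p.value),
                se = unname(tt$stderr), df = unname(tt$parameter))
  }
  structure(c(list(allele = allele), res,
              list(n_used = length(test) + length(control),
                   n_test = length(test), n_control = length(control),
                   mean_test = mean(test), mean_control = mean(control))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: s = %.4g [%.4g; %.4g], p = %.3g (n = %d)\n",
              x$allele, x$disadvantage, x$ci95[1], x$ci95[2], x$p_value, x$n_used))
  invisible(x)
}

#' Shapiro-Wilk normality check for selection coefficients
#'
#' Thin contract wrapper around the standard Shapiro-Wilk test, used to
#' verify that within-window replicate selection coefficients are compatible
#' with Gaussian measurement noise.
#'
#' @param s numeric vector, 3 <= length <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(s) {
  stopifnot(is.numeric(s))
  if (length(s) < 3L || length(s) > 5000L)
    stop("sample size must be between 3 and 5000")
  if (stats::sd(s) == 0) stop("constant sample: normality undefined")
  sw <- stats::shapiro.test(s)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

#' Full competition-fitness chain for a trajectory table
#'
#' Runs [estimate_selection()], the per-group median-window outlier filter,
#' dye-batch normalization to the control strain, and the group comparison
#' of every test strain against the control.
#'
#' @inheritParams estimate_selection
#' @inheritParams normalize_to_reference
#' @inheritParams filter_outliers
#' @param var_equal see [compare_groups()].
#' @return data.frame with one row per test strain (`allele`,
#'   `disadvantage`, `ci_low`, `ci_high`, `n_used`, `p_value`) with the full
#'   `selection_result` objects in attribute `results` and the filtered,
#'   normalized estimates in attribute `estimates`.
#' @export
fit_competition <- function(traj, control = "tufA", window = 0.008,
                            method = c("ols", "endpoints"), var_equal = FALSE) {
  est <- estimate_selection(traj, method = method)
  est <- filter_outliers_grouped(est, window = window)
  est <- normalize_to_reference(est, control = control)
  ctrl <- est$s_norm[est$strain == control]
  strains <- setdiff(unique(est$strain), control)
  results <- lapply(strains, function(a)
    compare_groups(est$s_norm[est$strain == a], ctrl, var_equal = var_equal,
                   allele = a))
  out <- data.frame(allele = strains,
                    disadvantage = vapply(results, `[[`, 0, "disadvantage"),
                    ci_low = vapply(results, function(r) r$ci95[1], 0),
                    ci_high = vapply(results, function(r) r$ci95[2], 0),
                    n_used = vapply(results, `[[`, 0L, "n_used"),
                    p_value = vapply(results, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  attr(out, "results") <- setNames(results, strains)
  attr(out, "estimates") <- est
  out
}
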