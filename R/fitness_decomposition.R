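# Multiplicative per-codon fitness decomposition, the substitution-count
# regressions, additivity comparisons, correlation analyses and the
# theoretical anchors (Bulmer prediction, per-generation conversions).

#' Selective disadvantage per codon under the multiplicative model
#'
#' With relative fitness `omega = 1 - total_s` and `N` equal, independent
#' substitutions, `omega = (1 - s)^N`, so the per-codon cost is
#' `s = 1 - (1 - total_s)^(1/N)`. Exact inverse of [combine_fitness()] for
#' equal costs.
#'
#' @param total_s numeric in `[0, 1)`, total selective disadvantage per
#'   generation of the allele.
#' @param N positive integer, number of synonymous substitutions.
#' @return numeric per-codon selective disadvantage per generation.
#' @examples
#' per_codon_s(0.0072, 25)  # ~2.89e-4
#' @export
per_codon_s <- function(total_s, N) {
  stopifnot(is.numeric(total_s), is.numeric(N))
  if (any(!is.finite(total_s)) || any(total_s < 0) || any(total_s >= 1))
    stop("total_s must lie in [0, 1)")
  if (any(N < 1) || any(N != as.integer(N))) stop("N must be a positive integer")
  n <- max(length(total_s), length(N))
  total_s <- rep_len(total_s, n)
  N <- rep_len(N, n)
  out <- 1 - (1 - total_s)^(1 / N)
  out[N == 1] <- total_s[N == 1]  # exact identity, no float round trip
  out
}

#' Combine per-codon costs into a total relative fitness
#'
#' Independent substitutions multiply: `omega = prod(1 - s_i)`; with equal
#' costs this is `(1 - s)^N`. An empty list gives `omega = 1`.
#'
#' @param per_codon_costs numeric vector of per-codon costs, each in `[0, 1)`.
#' @return total relative fitness `omega` in `(0, 1]`.
#' @export
combine_fitness <- function(per_codon_costs) {
  stopifnot(is.numeric(per_codon_costs) || length(per_codon_costs) == 0L)
  if (any(per_codon_costs < 0) || any(per_codon_costs >= 1))
    stop("per-codon costs must lie in [0, 1)")
  prod(1 - per_codon_costs)
}

.regression_result <- function(fit, n) {
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 n = n, fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope = %.4g, intercept = %.4g, r2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Regress total selective disadvantage on substitution count
#'
#' Ordinary least squares of `total_s` on `N`, with intercept. The slope is
#' the regression estimate of the per-codon cost. By default the wild-type
#' point `(0, 0)` is included: the unedited allele is a genuine observation
#' of zero substitutions at zero cost.
#'
#' @param points data.frame with columns `N` and `total_s`.
#' @param include_origin logical, add the `(0, 0)` wild-type point
#'   (default `TRUE`).
#' @return a `regression_result` with `slope`, `intercept`, `r_squared`,
#'   `p_value`.
#' @examples
#' regress_s_vs_N(data.frame(N = c(12, 13, 25),
#'                           total_s = c(0.0030, 0.0025, 0.0072)))
#' @export
regress_s_vs_N <- function(points, include_origin = TRUE) {
  stopifnot(is.data.frame(points), all(c("N", "total_s") %in% names(points)))
  d <- data.frame(N = as.numeric(points$N), total_s = as.numeric(points$total_s))
  if (include_origin) d <- rbind(data.frame(N = 0, total_s = 0), d)
  if (nrow(d) < 3L) stop("need at least 3 points")
  if (stats::var(d$N) == 0) stop("degenerate: all N equal")
  .regression_result(stats::lm(total_s ~ N, data = d), nrow(d))
}

#' Ordinary least-squares correlation between two quantities
#'
#' OLS fit of `y` on `x` with the coefficient of determination and the
#' two-sided t-test p-value on the slope; used to relate per-codon costs to
#' log relative adaptiveness, translation-time increases, folding
#' free-energy changes and anti-SD hexamer counts.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `regression_result`.
#' @export
correlate <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in x")
  .regression_result(stats::lm(y ~ x), length(x))
}

#' Test additivity of partial-allele costs against the combined allele
#'
#' Compares the sum of the selective disadvantages of part-alleles (e.g. the
#' two half-gene designs, or two single-amino-acid designs) with the
#' disadvantage of the allele carrying all substitutions, by a two-sided
#' t-type test on summary statistics: the standard error of the sum is the
#' root-sum-square of the component standard errors and the degrees of
#' freedom follow Welch-Satterthwaite.
#'
#' @param parts list of `selection_result`s (from [compare_groups()]).
#' @param whole a `selection_result` for the combined allele.
#' @return list with `sum_parts`, `whole`, `difference`, `se`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
additivity_test <- function(parts, whole) {
  stopifnot(is.list(parts), length(parts) >= 2L,
            all(vapply(parts, inherits, TRUE, "selection_result")),
            inherits(whole, "selection_result"))
  comps <- c(parts, list(whole))
  se <- vapply(comps, `[[`, 0, "se")
  df <- vapply(comps, `[[`, 0, "df")
  if (any(!is.finite(se)) || any(se < 0) || any(!is.finite(df)))
    stop("missing dispersion information in a selection_result")
  sum_parts <- sum(vapply(parts, `[[`, 0, "disadvantage"))
  diff <- sum_parts - whole$disadvantage
  se_tot <- sqrt(sum(se^2))
  if (se_tot == 0) {
    p <- if (diff == 0) 1 else 0
    return(list(sum_parts = sum_parts, whole = whole$disadvantage,
                difference = diff, se = 0, t_statistic = NA_real_,
                df = NA_real_, p_value = p))
  }
  df_w <- se_tot^4 / sum(se^4 / df)
  tstat <- diff / se_tot
  list(sum_parts = sum_parts, whole = whole$disadvantage, difference = diff,
       se = se_tot, t_statistic = tstat, df = df_w,
       p_value = 2 * stats::pt(-abs(tstat), df_w))
}

#' Theoretical per-codon cost from protein abundance
#'
#' Selection-mutation-drift theory predicts that replacing one frequent
#' codon by a rare one, outside the initiation region, costs
#' `s = 0.01 * p`, where `p` is the relative abundance of the encoded
#' protein (fraction of total protein mass).
#'
#' @param p numeric in `[0, 1]`, relative protein abundance.
#' @return predicted selective disadvantage per codon per generation.
#' @examples
#' bulmer_prediction(0.09)  # 9e-4 for a protein at 9% of cell protein
#' @export
bulmer_prediction <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  0.01 * p
}

#' Convert a per-generation cost to doublings per hour
#'
#' @param s selective disadvantage per generation.
#' @param doublings_per_hour growth rate (> 0).
#' @return cost in doublings per hour, `s * doublings_per_hour`.
#' @export
per_generation_to_per_hour <- function(s, doublings_per_hour) {
  stopifnot(is.numeric(s), is.numeric(doublings_per_hour))
  if (any(doublings_per_hour <= 0)) stop("doublings_per_hour must be positive")
  s * doublings_per_hour
}

#' @rdname per_generation_to_per_hour
#' @export
per_hour_to_per_generation <- function(s, doublings_per_hour) {
  stopifnot(is.numeric(s), is.numeric(doublings_per_hour))
  if (any(doublings_per_hour <= 0)) stop("doublings_per_hour must be positive")
  s / doublings_per_hour
}
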