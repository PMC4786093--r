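test_that("noiseless trajectories recover the slope exactly", {
  expect_equal(estimate_s(exact_traj(0.003)), -0.003)
  expect_equal(estimate_s(exact_traj(0)), 0)
  expect_equal(estimate_s(exact_traj(0.003), method = "endpoints"), -0.003)
})

test_that("estimate_s validates its input", {
  expect_error(estimate_s(data.frame(generation = 0, ratio = 1)), "at least 2")
  expect_error(estimate_s(data.frame(generation = c(0, 0), ratio = c(1, 1))),
               "strictly increasing")
  expect_error(estimate_s(data.frame(generation = c(0, 10), ratio = c(1, -1))),
               "positive")
})

test_that("estimate_s is scale-equivariant and sign-flips under reciprocal", {
  tr <- exact_traj(0.004)
  tr$ratio <- tr$ratio * exp(rnorm(4, 0, 0.01))
  s <- estimate_s(tr)
  scaled <- tr; scaled$ratio <- tr$ratio * 57.3
  expect_equal(estimate_s(scaled), s)
  recip <- tr; recip$ratio <- 1 / tr$ratio
  expect_equal(estimate_s(recip), -s)
})

test_that("the OLS estimator is unbiased under Gaussian ln-ratio noise", {
  withr::with_seed(17, {
    gens <- c(0, 10, 20, 30)
    shat <- replicate(1000, {
      # true s = -0.005, Gaussian ln-ratio noise sigma = 0.02
      estimate_s(data.frame(generation = gens,
                            ratio = exp(-0.005 * gens + rnorm(4, 0, 0.02))))
    })
    se_mean <- sd(shat) / sqrt(length(shat))
    expect_lt(abs(mean(shat) - (-0.005)), 3 * se_mean)
  })
})

test_that("the median-window filter removes exactly the flagged values", {
  tight <- c(-0.001, 0.0005, 0.002, -0.0015, 0.001, 0, 0.0005, -0.002,
             0.0018, -0.0012, 0.0002, -0.0008)
  f <- filter_outliers(tight, window = 0.008)
  expect_length(f$removed, 0L)

  x <- c(tight, median(tight) + 0.01)
  f2 <- filter_outliers(x, window = 0.008)
  expect_equal(f2$removed_index, length(x))

  # brute-force check on seeded contaminated groups
  withr::with_seed(23, {
    for (i in 1:20) {
      g <- rnorm(12, 0, 0.003)
      idx <- sample(12, 2)
      g[idx] <- g[idx] + 0.02
      f3 <- filter_outliers(g, window = 0.008)
      expect_equal(f3$removed_index, which(abs(g - median(g)) > 0.008))
    }
  })

  # idempotence: filtering the kept values removes nothing further
  f4 <- filter_outliers(f2$kept, window = 0.008)
  expect_length(f4$removed, 0L)
})

test_that("normalization maps the control mean to zero per dye batch", {
  est <- data.frame(
    strain = rep(c("tufA", "syn"), each = 4),
    dye = rep(c("YFP", "YFP", "BFP", "BFP"), 2),
    replicate = rep(1:2, 4),
    s = c(-0.001, -0.001, -0.002, -0.002, -0.004, -0.004, -0.006, -0.006))
  out <- normalize_to_reference(est, control = "tufA")
  expect_equal(out$s_norm[out$strain == "tufA"], rep(0, 4))
  expect_equal(out$s_norm[out$strain == "syn" & out$dye == "YFP"],
               rep(-0.003, 2))
  expect_equal(out$s_norm[out$strain == "syn" & out$dye == "BFP"],
               rep(-0.004, 2))
  expect_error(normalize_to_reference(est[est$strain == "syn", ]),
               "dye batch")
})

test_that("group comparison reports a positive cost with CI and p-value", {
  a <- c(-0.001, 0.002, 0, -0.002, 0.001, 0.0007)
  expect_equal(compare_groups(a, a)$disadvantage, 0)
  expect_equal(compare_groups(a, a)$p_value, 1)

  r <- compare_groups(a - 0.0072, a)
  expect_equal(r$disadvantage, 0.0072)
  expect_true(r$ci95[1] <= r$disadvantage && r$disadvantage <= r$ci95[2])

  expect_warning(z <- compare_groups(rep(1, 3), rep(1, 3)), "zero variance")
  expect_equal(z$ci95, c(0, 0))
  expect_equal(z$p_value, 1)
})

test_that("group-comparison CIs cover a true shift at the nominal rate", {
  withr::with_seed(41, {
    cover <- replicate(1000, {
      ctrl <- rnorm(24, 0, 0.0025)
      test <- rnorm(24, -0.003, 0.0025)
      ci <- compare_groups(test, ctrl)$ci95
      ci[1] <= 0.003 && 0.003 <= ci[2]
    })
    expect_gte(mean(cover), 0.93)
    expect_lte(mean(cover), 0.97)
  })
})

test_that("normality check delegates Shapiro-Wilk and guards its domain", {
  withr::with_seed(53, {
    nc <- normality_check(rnorm(168, 0, 0.0025))
    expect_gt(nc$W, 0.97)
    expect_gt(nc$p, 0.01)
    # heavy contamination is flagged in the majority of seeds
    rej <- replicate(40, {
      x <- rnorm(100); x[1:10] <- x[1:10] + 8
      normality_check(x)$p < 0.05
    })
    expect_gt(mean(rej), 0.9)
  })
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
})
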