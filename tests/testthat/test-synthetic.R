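test_that("all generators are seed-deterministic", {
  cfg <- simulation_config(seed = 99)
  g1 <- make_biased_gene_set(cfg, n_genes = 3, gene_length = 50)
  g2 <- make_biased_gene_set(cfg, n_genes = 3, gene_length = 50)
  expect_identical(vapply(g1, `[[`, "", "seq"), vapply(g2, `[[`, "", "seq"))

  t1 <- simulate_competitions(cfg)
  t2 <- simulate_competitions(cfg)
  expect_identical(t1, t2)
  expect_false(identical(t1$ratio,
                         simulate_competitions(simulation_config(seed = 100))$ratio))

  q1 <- simulate_qpcr(cfg, data.frame(allele = "a", fold_change = 1, half_life = 3))
  q2 <- simulate_qpcr(cfg, data.frame(allele = "a", fold_change = 1, half_life = 3))
  expect_identical(q1, q2)
})

test_that("generated genes carry the configured codon bias", {
  # extreme bias: all mass on one codon per family -> RSCU = family size
  probs <- lapply(codonfit:::.default_codon_probs(), function(p) {
    q <- p * 0; q[which.max(p)] <- 1; q
  })
  cfg <- simulation_config(seed = 12, codon_probs = probs)
  genes <- make_biased_gene_set(cfg, n_genes = 10, gene_length = 100)
  tab <- compute_rscu(count_codons(genes, exclude_first = 0))
  used <- tab[!is.na(tab$rscu) & tab$count > 0, ]
  expect_equal(used$rscu, as.numeric(used$family_size))

  # uniform probabilities -> RSCU near 1 everywhere at large n
  uni <- lapply(codonfit:::.default_codon_probs(), function(p) p * 0 + 1 / length(p))
  cfgu <- simulation_config(seed = 13, codon_probs = uni)
  genesu <- make_biased_gene_set(cfgu, n_genes = 60, gene_length = 200)
  tabu <- compute_rscu(count_codons(genesu, exclude_first = 0))
  expect_lt(max(abs(tabu$rscu - 1), na.rm = TRUE), 0.35)

  expect_error(simulation_config(codon_probs = list(L = c(CTG = 0.5))),
               "sum to 1")
})

test_that("zero-noise trajectories are exactly log-linear at the true slope", {
  cfg <- simulation_config(seed = 3, sigma_lnratio = 0, outlier_prob = 0,
                           dye_effect = 0, disadvantages = c(a = 0.0072))
  tr <- simulate_competitions(cfg)
  for (rep_i in 1:3) {
    one <- tr[tr$replicate == rep_i & tr$dye == "YFP", ]
    expect_equal(estimate_s(one[, c("generation", "ratio")]), -0.0072)
  }
})

test_that("dye effects cancel through control normalization", {
  cfg <- simulation_config(seed = 29, sigma_lnratio = 0, outlier_prob = 0,
                           dye_effect = 0.002,
                           disadvantages = c(tufA = 0, syn = 0.004))
  fit <- suppressWarnings(fit_competition(simulate_competitions(cfg)))
  expect_equal(fit$disadvantage[fit$allele == "syn"], 0.004, tolerance = 1e-10)
})

test_that("control-group slopes are normal with the configured spread", {
  cfg <- simulation_config(seed = 37, outlier_prob = 0, replicates = 84,
                           disadvantages = c(tufA = 0))
  est <- estimate_selection(simulate_competitions(cfg))
  expect_equal(nrow(est), 168L)
  # slope sd should match sigma / sqrt(sum((g - mean(g))^2)) = sigma/sqrt(500)
  per_dye <- split(est$s, est$dye)
  for (s in per_dye)
    expect_equal(sd(s), cfg$sigma_lnratio / sqrt(500), tolerance = 0.25)
  nc <- normality_check(est$s - ave(est$s, est$dye))
  expect_gt(nc$p, 0.001)
  # virtually all clean slopes sit within the 0.8%/generation filter window
  expect_equal(unname(vapply(per_dye, function(s)
    mean(abs(s - median(s)) <= 0.008), 0)), c(1, 1))
})

test_that("injected outlier replicates are recorded and visibly shifted", {
  cfg <- simulation_config(seed = 57, outlier_prob = 0.25,
                           disadvantages = c(tufA = 0, syn = 0.0072))
  tr <- simulate_competitions(cfg)
  out <- attr(tr, "outliers")
  expect_gt(nrow(out), 0L)
  est <- estimate_selection(tr)
  key <- paste(est$strain, est$dye, est$replicate)
  flagged <- paste(out$strain, out$dye, out$replicate)
  est <- filter_outliers_grouped(est)
  expect_true(all(!est$kept[key %in% flagged]))
})

test_that("simulated qPCR tables honor efficiency-2 amplification", {
  cfg <- simulation_config(seed = 8, ct_sigma = 0)
  ct <- simulate_qpcr(cfg, data.frame(allele = c("wt", "half"),
                                      fold_change = c(1, 0.5),
                                      half_life = c(4, 4)))
  expect_equal(relative_abundance(ct, "tuf", c("cysG", "hcaT", "idnT"),
                                  "half", "wt"), 0.5)
  expect_equal(half_life(ct, "tuf", "tmRNA", "wt")$half_life_min, 4)
})
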