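test_that("N-terminal exclusion and stop handling in codon counts", {
  g <- coding_sequence("g", strrep("CTG", 41))
  tab <- count_codons(g, exclude_first = 40)
  expect_equal(tab$count[tab$codon == "CUG"], 1L)
  expect_equal(sum(tab$count), 1L)

  g2 <- coding_sequence("g2", "ATGTTATAA")
  tab2 <- count_codons(list(g2, g2), exclude_first = 0)
  expect_equal(tab2$count[tab2$codon == "AUG"], 2L)
  expect_equal(tab2$count[tab2$codon == "UUA"], 2L)
  expect_equal(sum(tab2$count), 4L)              # stops not in families
  expect_equal(sum(attr(tab2, "stop_counts")), 2L)

  expect_error(count_codons(g2, exclude_first = 5), "cannot exclude")
})

test_that("codon counts match a brute-force triplet tally and are additive", {
  genes <- lapply(1:10, function(i) random_cds(paste0("g", i), 100, seed = 100 + i))
  tab <- count_codons(genes, exclude_first = 40)
  oracle <- brute_count(vapply(genes, `[[`, "", "seq"), 40)
  oracle <- oracle[Biostrings::GENETIC_CODE[names(oracle)] != "*"]
  got <- setNames(tab$count, as_dna(tab$codon))
  expect_equal(got[names(oracle)], oracle, ignore_attr = TRUE)
  expect_equal(sum(got), sum(oracle))

  # additivity over gene lists
  a <- count_codons(genes[1:4], 40)$count
  b <- count_codons(genes[5:10], 40)$count
  expect_equal(a + b, tab$count)
})

test_that("RSCU follows the count * family_size / total formula", {
  # two-codon family (Lys: AAA/AAG) with 5/5 -> both 1; 10/0 -> 2/0
  g_even <- coding_sequence("e", paste(strrep("AAA", 5), strrep("AAG", 5), sep = ""))
  r <- compute_rscu(count_codons(g_even, 0))
  expect_equal(r$rscu[r$codon %in% c("AAA", "AAG")], c(1, 1))

  g_skew <- coding_sequence("s", strrep("AAA", 10))
  r2 <- compute_rscu(count_codons(g_skew, 0))
  expect_equal(r2$rscu[r2$codon == "AAA"], 2)
  expect_equal(r2$rscu[r2$codon == "AAG"], 0)
  expect_true(all(is.na(r2$rscu[r2$amino_acid == "L"])))  # unseen family

  # six-codon Leu family against the direct formula on a seeded gene set
  genes <- lapply(1:5, function(i) random_cds(paste0("g", i), 120, seed = 200 + i))
  tab <- compute_rscu(count_codons(genes, 0))
  leu <- tab[tab$amino_acid == "L", ]
  expect_equal(leu$rscu, leu$count * 6 / sum(leu$count))
})

test_that("RSCU sums to family size within every used family", {
  genes <- lapply(1:6, function(i) random_cds(paste0("g", i), 150, seed = 300 + i))
  tab <- compute_rscu(count_codons(genes, 10))
  sums <- tapply(tab$rscu, tab$amino_acid, sum)
  sizes <- tapply(tab$family_size, tab$amino_acid, max)
  used <- !is.na(sums)
  expect_equal(as.numeric(sums[used]), as.numeric(sizes[used]),
               tolerance = 1e-9)
})

test_that("relative adaptiveness anchors the reference codon at wa = 1", {
  # family with RSCU 1.8 / 0.2 (9:1 usage of a two-codon family)
  g <- coding_sequence("g", paste0(strrep("AAA", 9), "AAG"))
  wa <- compute_wa(compute_rscu(count_codons(g, 0)))
  k <- wa[wa$amino_acid == "K", ]
  expect_equal(k$rscu, c(1.8, 0.2))
  expect_identical(k$wa[k$codon == "AAA"], 1)
  expect_identical(k$log_wa[k$codon == "AAA"], 0)
  expect_equal(k$wa[k$codon == "AAG"], 1 / 9)
  expect_equal(k$log_wa[k$codon == "AAG"], -0.954, tolerance = 1e-3)

  # all-equal family: wa = 1 throughout
  g2 <- coding_sequence("g2", "AAAAAG")
  wa2 <- compute_wa(compute_rscu(count_codons(g2, 0)))
  expect_equal(wa2$wa[wa2$amino_acid == "K"], c(1, 1))

  # explicit reference override
  wa3 <- compute_wa(compute_rscu(count_codons(g, 0)), reference = "AAG")
  expect_identical(wa3$wa[wa3$codon == "AAG"], 1)
  expect_equal(wa3$wa[wa3$codon == "AAA"], 9)
})

test_that("wa is invariant to scaling all counts in a family", {
  genes <- lapply(1:3, function(i) random_cds(paste0("g", i), 90, seed = 400 + i))
  one <- compute_wa(compute_rscu(count_codons(genes, 0)))
  trip <- compute_wa(compute_rscu(count_codons(c(genes, genes, genes), 0)))
  expect_equal(one$wa, trip$wa, tolerance = 1e-12)
})

test_that("RSCU converges to probability * family_size for generated usage", {
  cfg <- simulation_config(seed = 11, n_genes = 60, gene_length = 200)
  genes <- make_biased_gene_set(cfg)
  tab <- compute_rscu(count_codons(genes, 0))
  leu <- tab[tab$amino_acid == "L", ]
  p <- cfg$codon_probs$L[as_dna(leu$codon)]
  # ~2000 Leu codons: relative error shrinks as 1/sqrt(n)
  expect_equal(leu$rscu, unname(p * 6), tolerance = 0.1)
})
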