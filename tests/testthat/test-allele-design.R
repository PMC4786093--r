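test_that("the protected prefix shields leading codons from replacement", {
  # CUG at codon 10 (inside prefix) and 45 (editable), filler AAA
  cod <- rep("AAA", 50)
  cod[c(10, 45)] <- "CTG"
  p <- coding_sequence("p", paste(cod, collapse = ""))
  a <- design_allele(p, design_spec(c(Leu = "UUA"), protected_prefix = 40))
  expect_equal(a$N, 1L)
  expect_equal(a$substitutions$codon_index, 45L)
  expect_equal(a$substitutions$from, "CUG")
  expect_equal(a$substitutions$to, "UUA")
})

test_that("replacing a codon by itself is a no-op with N = 0", {
  cod <- rep("AAA", 50); cod[45] <- "TTA"
  p <- coding_sequence("p", paste(cod, collapse = ""))
  a <- design_allele(p, design_spec(c(Leu = "UUA")))
  expect_equal(a$N, 0L)
  expect_equal(a$seq$seq, p$seq)
})

test_that("designed substitution count matches a brute-force scan", {
  p <- random_cds("p", 400, seed = 42)
  a <- design_allele(p, design_spec(c(Leu = "CUA"), protected_prefix = 40))
  cod <- codons(p)
  leu <- Biostrings::GENETIC_CODE[cod] == "L" & cod != "CTA"
  leu[1:40] <- FALSE
  leu[length(cod)] <- FALSE  # stop never edited
  expect_equal(a$N, sum(leu))
  expect_identical(translate_cds(a$seq), translate_cds(p))
})

test_that("source filters restrict replacement to one source codon", {
  cod <- rep("AAA", 60)
  cod[c(45, 50)] <- "CGT"; cod[55] <- "CGC"
  p <- coding_sequence("p", paste(cod, collapse = ""))
  a <- design_allele(p, design_spec(c(Arg = "CGG"),
                                    source_filter = c(Arg = "CGU")))
  expect_equal(a$substitutions$codon_index, c(45L, 50L))
  expect_true(all(a$substitutions$from == "CGU"))
})

test_that("invalid designs are rejected", {
  p <- random_cds("p", 60, seed = 5)
  expect_error(design_spec(c(Leu = "CCG")), "not synonymous")
  expect_error(design_allele(p, design_spec(c(Leu = "UUA"),
                                            region = c(10, 100))),
               "region outside gene")
})

test_that("design is idempotent and protein-preserving across seeded genes", {
  for (i in 1:20) {
    p <- random_cds(paste0("p", i), 150, seed = 1000 + i)
    spec <- design_spec(c(Leu = "UUA", Pro = "CCA"))
    a <- design_allele(p, spec)
    expect_identical(translate_cds(a$seq), translate_cds(p))
    a2 <- design_allele(a$seq, spec)
    expect_equal(a2$N, 0L)
    expect_equal(a2$seq$seq, a$seq$seq)
  }
})

test_that("multi-amino-acid designs are unions of single-amino-acid designs", {
  p <- random_cds("p", 200, seed = 77)
  both <- design_allele(p, design_spec(c(Leu = "UUG", Pro = "CCU")))
  leu <- design_allele(p, design_spec(c(Leu = "UUG")))
  pro <- design_allele(p, design_spec(c(Pro = "CCU")))
  expect_equal(both$N, leu$N + pro$N)
  expect_equal(both$substitutions,
               (function(d) d[order(d$codon_index), ])(
                 rbind(leu$substitutions, pro$substitutions)),
               ignore_attr = TRUE)
})

test_that("half-region designs partition the full design at any boundary", {
  p <- random_cds("p", 120, seed = 9)
  spec <- design_spec(c(Leu = "CUC"))
  full <- design_allele(p, spec)
  # default midpoint split
  halves <- split_regions(p, spec)
  n1 <- design_allele(p, halves$first)$N
  n2 <- design_allele(p, halves$second)$N
  expect_equal(n1 + n2, full$N)
  # exhaustive boundary sweep
  for (b in seq(42, 115, by = 7)) {
    h <- split_regions(p, spec, boundary = b)
    expect_equal(design_allele(p, h$first)$N + design_allele(p, h$second)$N,
                 full$N)
  }
  # no targeted codons at all -> both halves empty
  q <- coding_sequence("q", paste(c(rep("AAA", 80), "TAA"), collapse = ""))
  hq <- split_regions(q, spec)
  expect_equal(design_allele(q, hq$first)$N, 0L)
  expect_equal(design_allele(q, hq$second)$N, 0L)
})

test_that("diff_alleles reports codon-level differences and round-trips", {
  p <- random_cds("p", 90, seed = 21)
  expect_equal(nrow(diff_alleles(p, p)), 0L)

  cod <- codons(p); cod[50] <- "GGG"
  q <- coding_sequence("q", paste(cod, collapse = ""))
  d <- diff_alleles(q, p)
  expect_equal(d$codon_index, 50L)
  expect_equal(d$to, "GGG")

  a <- design_allele(p, design_spec(c(Val = "GUC")))
  expect_equal(diff_alleles(a$seq, p), a$substitutions, ignore_attr = TRUE)

  short <- coding_sequence("s", "ATGTAA")
  expect_error(diff_alleles(p, short), "length")
})
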