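# Shared test fixtures, all generated in code.

# a random in-frame CDS of `n` codons (sense codons + terminal stop)
random_cds <- function(id, n, seed) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(seed, {
    coding_sequence(id, paste(c(sample(sense, n - 1, replace = TRUE), "TAA"),
                              collapse = ""))
  })
}

# independent brute-force codon tally by string slicing
brute_count <- function(seqs, exclude_first) {
  tallies <- list()
  for (s in seqs) {
    i <- 3 * exclude_first + 1
    while (i + 2 <= nchar(s)) {
      cod <- substr(s, i, i + 2)
      tallies[[cod]] <- (tallies[[cod]] %||% 0) + 1
      i <- i + 3
    }
  }
  unlist(tallies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless competition trajectory for one replicate
exact_traj <- function(s, gens = c(0, 10, 20, 30), r0 = 1) {
  data.frame(generation = gens, ratio = r0 * exp(-s * gens))
}
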