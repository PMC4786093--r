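# Synthetic-data generators: every input the pipeline consumes can be
# simulated with the statistical structure the analysis assumes, so the
# whole chain is testable offline.

# run code with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# default per-family codon probabilities: one strongly preferred (optimal)
# codon per family carrying 75% of the mass, the rest shared equally —
# emulating the extreme bias of highly expressed bacterial genes
.default_optimal <- c(A = "GCG", R = "CGT", N = "AAC", D = "GAC", C = "TGC",
                      Q = "CAG", E = "GAA", G = "GGC", H = "CAC", I = "ATC",
                      L = "CTG", K = "AAA", M = "ATG", F = "TTC", P = "CCG",
                      S = "TCT", T = "ACC", W = "TGG", Y = "TAC", V = "GTT")

.default_codon_probs <- function(optimal_mass = 0.75) {
  info <- .codon_info()
  lapply(split(info$codon, info$amino_acid), function(cods) {
    opt <- .default_optimal[.genetic_code()[cods[1L]]]
    p <- rep((1 - optimal_mass) / max(1L, length(cods) - 1L), length(cods))
    names(p) <- cods
    if (length(cods) == 1L) p[] <- 1 else p[opt] <- optimal_mass
    p
  })
}

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the design of the competition study the pipeline
#' analyzes: twelve replicate cultures per strain per dye orientation with a
#' dye swap (24 effective replicates), sampling every 10 generations over 30
#' generations of serial transfer, Gaussian noise on each ln-ratio
#' observation of 0.025 (about 0.25% per generation on fitted slopes),
#' occasional replicates hit by a persistent slope shift of 0.015 per
#' generation (a secondary genetic change, probability 0.02), and a small
#' additive marker (dye) effect that the normalization stage must cancel.
#'
#' @param seed integer RNG seed; identical seeds give identical outputs.
#' @param gene_length gene length in codons for [make_biased_gene_set()].
#' @param n_genes number of reference genes generated.
#' @param codon_probs list per amino acid of named codon probability vectors
#'   (each summing to 1); default: 75% of the mass on one optimal codon.
#' @param disadvantages named numeric vector of true per-allele selective
#'   disadvantages per generation (default: one wild-type control at 0 and
#'   one synonymous allele at 0.0072, the scale of a fully recoded
#'   high-expression allele).
#' @param sigma_lnratio standard deviation of the noise added to each
#'   ln-ratio observation (default 0.025).
#' @param outlier_prob probability a replicate carries a persistent slope
#'   shift (default 0.02).
#' @param outlier_jump magnitude of that shift per generation (default
#'   0.015; sign random).
#' @param replicates replicate cultures per strain per dye batch (default 12).
#' @param dye_swap logical, emit both dye orientations (default TRUE).
#' @param dye_effect additive slope effect of the dye orientation (default
#'   0.001 per generation, applied to one orientation).
#' @param generations sampling times (default `c(0, 10, 20, 30)`).
#' @param ct_sigma Gaussian noise on each qPCR Ct value (default 0.1).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              gene_length = 300L,
                              n_genes = 40L,
                              codon_probs = .default_codon_probs(),
                              disadvantages = c(tufA = 0, syn = 0.0072),
                              sigma_lnratio = 0.025,
                              outlier_prob = 0.02,
                              outlier_jump = 0.015,
                              replicates = 12L,
                              dye_swap = TRUE,
                              dye_effect = 0.001,
                              generations = c(0, 10, 20, 30),
                              ct_sigma = 0.1) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            gene_length >= 2L, n_genes >= 1L,
            sigma_lnratio >= 0, outlier_prob >= 0, outlier_prob <= 1,
            outlier_jump >= 0, replicates >= 2L, ct_sigma >= 0,
            length(generations) >= 2L, !is.unsorted(generations))
  ok <- vapply(codon_probs, function(p)
    abs(sum(p) - 1) < 1e-8 && all(p >= 0), TRUE)
  if (!all(ok))
    stop("codon_probs must sum to 1 within each family: ",
         paste(names(codon_probs)[!ok], collapse = ", "))
  structure(list(seed = as.integer(seed), gene_length = as.integer(gene_length),
                 n_genes = as.integer(n_genes), codon_probs = codon_probs,
                 disadvantages = disadvantages,
                 sigma_lnratio = sigma_lnratio, outlier_prob = outlier_prob,
                 outlier_jump = outlier_jump, replicates = as.integer(replicates),
                 dye_swap = dye_swap, dye_effect = dye_effect,
                 generations = as.numeric(generations), ct_sigma = ct_sigma),
            class = "simulation_config")
}

#' Generate a codon-usage-biased reference gene set
#'
#' Genes are drawn codon-wise: a uniformly chosen amino acid per position,
#' then a codon from that family's probability vector; a terminal stop is
#' appended. Sense-only sampling guarantees no internal stops. A stand-in
#' for a highly expressed reference gene set (elongation factors, ribosomal
#' proteins).
#'
#' @param config a [simulation_config()].
#' @param n_genes,gene_length optional overrides of the config values.
#' @return list of `coding_sequence` objects.
#' @export
make_biased_gene_set <- function(config, n_genes = config$n_genes,
                                 gene_length = config$gene_length) {
  stopifnot(inherits(config, "simulation_config"))
  probs <- config$codon_probs
  aas <- names(probs)
  .with_seed(config$seed, {
    lapply(seq_len(n_genes), function(i) {
      aa <- sample(aas, gene_length - 1L, replace = TRUE)
      cod <- vapply(aa, function(a)
        sample(names(probs[[a]]), 1L, prob = probs[[a]]), character(1L))
      coding_sequence(sprintf("refgene_%03d", i),
                      paste(c(cod, "TAA"), collapse = ""))
    })
  })
}

#' Simulate competition trajectories
#'
#' For every allele and dye orientation, `replicates` cultures are simulated
#' with `ln ratio(g) = -(s_true + dye + jump) * g + e_g`, sampled at the
#' configured generations, with i.i.d. Gaussian observation noise `e_g`.
#' One dye orientation carries the additive `dye_effect` on the slope
#' (cancelled downstream by normalization to the control strain of the same
#' batch). With probability `outlier_prob` a replicate receives a persistent
#' slope shift of `outlier_jump` (random sign), emulating a secondary
#' genetic change in that culture.
#'
#' @param config a [simulation_config()].
#' @param disadvantages named numeric vector allele -> true selective
#'   disadvantage per generation in `[0, 0.05]` (default from the config).
#' @return data.frame with columns `strain`, `dye`, `replicate`,
#'   `generation`, `ratio`; attribute `outliers` marks the injected outlier
#'   replicates (data.frame `strain`, `dye`, `replicate`, `shift`).
#' @export
simulate_competitions <- function(config, disadvantages = config$disadvantages) {
  stopifnot(inherits(config, "simulation_config"),
            !is.null(names(disadvantages)),
            all(disadvantages >= 0), all(disadvantages <= 0.05))
  gens <- config$generations
  dyes <- if (config$dye_swap) c("YFP", "BFP") else "YFP"
  .with_seed(config$seed, {
    rows <- list()
    out_rows <- list()
    for (allele in names(disadvantages)) {
      for (dye in dyes) {
        dye_eff <- if (dye == "YFP") config$dye_effect else 0
        for (rep_i in seq_len(config$replicates)) {
          jump <- 0
          if (stats::runif(1L) < config$outlier_prob) {
            jump <- sample(c(-1, 1), 1L) * config$outlier_jump
            out_rows[[length(out_rows) + 1L]] <-
              data.frame(strain = allele, dye = dye, replicate = rep_i,
                         shift = jump, stringsAsFactors = FALSE)
          }
          slope <- -(disadvantages[[allele]] + dye_eff + jump)
          lnr <- slope * gens +
            stats::rnorm(length(gens), 0, config$sigma_lnratio)
          rows[[length(rows) + 1L]] <-
            data.frame(strain = allele, dye = dye, replicate = rep_i,
                       generation = gens, ratio = exp(lnr),
                       stringsAsFactors = FALSE)
        }
      }
    }
    traj <- do.call(rbind, rows)
    attr(traj, "outliers") <- if (length(out_rows) > 0L)
      do.call(rbind, out_rows)
    else data.frame(strain = character(), dye = character(),
                    replicate = integer(), shift = numeric())
    traj
  })
}

#' Simulate a rifampicin run-out qPCR Ct table
#'
#' Reference genes sit at a stable baseline Ct; the target gene starts at
#' `baseline - log2(fold_change)` and rises by `t / half_life` cycles per
#' minute of decay (efficiency-2 amplification). Technical dilutions shift
#' Ct by `log2(dilution)`. Gaussian noise `ct_sigma` is added per well.
#'
#' @param config a [simulation_config()].
#' @param alleles data.frame with columns `allele`, `fold_change` (> 0,
#'   target mRNA level relative to the calibrator) and `half_life` (> 0,
#'   minutes).
#' @param reference_genes reference gene names (default the four-gene panel
#'   `cysG`, `hcaT`, `idnT`, `tmRNA`).
#' @param timepoints minutes (default `c(0, 4, 8, 12)`).
#' @param dilutions fold dilutions per well (default `c(1, 10, 100)`).
#' @param baseline_ct baseline cycle threshold (default 20).
#' @return data.frame with columns `sample`, `gene`, `timepoint_min`,
#'   `dilution`, `ct`.
#' @export
simulate_qpcr <- function(config, alleles,
                          reference_genes = c("cysG", "hcaT", "idnT", "tmRNA"),
                          timepoints = c(0, 4, 8, 12),
                          dilutions = c(1, 10, 100),
                          baseline_ct = 20) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(alleles),
            all(c("allele", "fold_change", "half_life") %in% names(alleles)),
            all(alleles$half_life > 0), all(alleles$fold_change > 0))
  .with_seed(config$seed + 1L, {
    grid <- expand.grid(sample = alleles$allele,
                        gene = c("tuf", reference_genes),
                        timepoint_min = timepoints,
                        dilution = dilutions,
                        stringsAsFactors = FALSE)
    i <- match(grid$sample, alleles$allele)
    is_target <- grid$gene == "tuf"
    ct <- rep(baseline_ct, nrow(grid))
    ct[is_target] <- baseline_ct - log2(alleles$fold_change[i[is_target]]) +
      grid$timepoint_min[is_target] / alleles$half_life[i[is_target]]
    ct <- ct + log2(grid$dilution) +
      stats::rnorm(nrow(grid), 0, config$ct_sigma)
    grid$ct <- ct
    grid
  })
}
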