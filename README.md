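# codonfit

Tools for quantifying the selective value of synonymous codon usage bias in
highly expressed bacterial genes.

Synonymous codons encode identical proteins, yet fast-growing bacteria use
them at very unequal frequencies, most strongly in their most highly
expressed genes. `codonfit` implements the full computational chain of the
experimental approach that measures this selection directly: recode a highly
expressed gene (the classic target is *tuf*, encoding elongation factor
EF-Tu) with non-optimal synonymous codons, compete the recoded strain
against the wild type, and convert the competition outcome into a selection
coefficient per synonymous codon.

## What the package computes

* **Synonymous allele design** — systematic codon replacement behind a
  protected 40-codon 5' prefix, with source-codon filters, half-gene
  regions and multi-amino-acid combinations; protein identity verified,
  substitution count *N* reported from the actual diff
  (`design_spec()`, `design_allele()`, `split_regions()`, `diff_alleles()`).
* **Codon-usage statistics** — codon counts with N-terminal exclusion,
  RSCU, and relative adaptiveness
  *w*<sub>a</sub> = RSCU<sub>syn</sub>/RSCU<sub>wt</sub> with
  log<sub>10</sub>(*w*<sub>a</sub>) from a highly expressed reference gene
  set (`count_codons()`, `compute_rscu()`, `compute_wa()`).
* **Translation kinetics** — the increase in decoding time
  Δ*t*<sub>trans</sub> = 1/*n*<sub>syn</sub> − 1/*n*<sub>wt</sub> from
  pooled tRNA concentrations with data-driven wobble recognition
  (`delta_t_trans()`).
* **Sequence features** — anti-Shine-Dalgarno hexamer scanning at every
  offset with a deterministic nearest-neighbor energy model, and ingestion
  of precomputed mRNA folding ΔΔG tables (`scan_anti_sd()`, `load_ddg()`).
* **Competition fitness** — ln-ratio slope estimation, the
  0.8%-per-generation median outlier filter, dye-swap normalization to the
  wild-type control, and Welch group comparison with 95% CI
  (`estimate_s()`, `filter_outliers()`, `normalize_to_reference()`,
  `compare_groups()`, `fit_competition()`).
* **Fitness decomposition** — the multiplicative model
  ω = Π(1 − *s*<sub>i</sub>), per-codon cost
  *s* = 1 − ω<sup>1/N</sup>, cost-vs-N regressions, additivity tests,
  correlations, the selection-mutation-drift prediction *s* = 0.01 *p*, and
  generation/hour conversions (`per_codon_s()`, `regress_s_vs_N()`,
  `additivity_test()`, `correlate()`, `bulmer_prediction()`).
* **mRNA quantification** — ΔΔCt relative abundance and rifampicin run-out
  half-lives (`relative_abundance()`, `half_life()`).
* **Synthetic data** — generators for biased gene sets, competition
  trajectories (noise, outliers, dye effects) and qPCR tables, so the whole
  chain runs and is testable offline (`simulation_config()`,
  `make_biased_gene_set()`, `simulate_competitions()`, `simulate_qpcr()`).

An umbrella `run_pipeline()` ties the stages together from a YAML or list
config, and `inst/cli/codonfit.R` exposes the stages as shell subcommands
(`rscu`, `design`, `kinetics`, `scan-sd`, `fit-competition`, `decompose`,
`correlate`, `halflife`, `simulate`, `run`).

## Worked example

Simulate a competition study (24 effective replicates, dye swap, outlier
contamination) for one recoded allele with a true cost of 0.0072 per
generation, then recover it and decompose it per codon:

```r
library(codonfit)

cfg  <- simulation_config(seed = 42, disadvantages = c(tufA = 0, LeuUUA = 0.0072))
traj <- simulate_competitions(cfg)
fit  <- fit_competition(traj, control = "tufA")
print(fit, digits = 3)
#>   allele disadvantage  ci_low ci_high n_used  p_value
#> 1 LeuUUA      0.00729 0.00658 0.00799     46 2.72e-24

per_codon_s(fit$disadvantage, 25)
#> [1] 0.000293
```

The estimated disadvantage (0.00729 per generation, 95% CI 0.00658–0.00799)
covers the simulated truth; `n_used = 46` shows the median filter removed
two contaminated replicates out of 48. Spread over the 25 substituted
leucine codons, the cost is ~2.9 × 10⁻⁴ per codon per generation.

Regressing total cost on substitution count across the full/half-gene
allele series (with the wild-type point at the origin) estimates the same
per-codon cost from the slope:

```r
regress_s_vs_N(data.frame(N = c(12, 13, 25),
                          total_s = c(0.0030, 0.0025, 0.0072)))
#> <regression> slope = 0.0002867, intercept = -0.0004093, r2 = 0.961, p = 0.0195 (n = 4)
```

For a protein at 9% of total cell protein, selection-mutation-drift theory
predicts `bulmer_prediction(0.09)` = 9 × 10⁻⁴ per codon per generation —
the same order as the measured values; and at 3 doublings per hour a cost
of 2 × 10⁻⁴ per generation converts to
`per_generation_to_per_hour(2e-4, 3)` = 6 × 10⁻⁴ doublings per hour.

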