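---
title: "Quantifying selection on synonymous codon usage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying selection on synonymous codon usage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonfit)
```

# The scientific problem

Synonymous codons encode the same amino acid but are used at very unequal
frequencies, and in fast-growing bacteria the bias is strongest in highly
expressed genes. `codonfit` implements the computational chain needed to
*measure* the selective value of that bias experimentally: design synonymous
alleles of a highly expressed gene (the canonical target being *tuf*,
encoding elongation factor EF-Tu), estimate the fitness cost of each allele
from head-to-head growth competitions, decompose the cost into a per-codon
selection coefficient, and relate the per-codon costs to codon-usage
statistics, tRNA availability and sequence features that could confound the
interpretation.

# The fitness model

A strain whose redesigned gene carries $N$ synonymous substitutions has
relative fitness

$$\omega \;=\; \prod_{i=1}^{N} (1 - s_i),$$

assuming the substitutions act independently and multiplicatively. If all
substitutions of one type contribute equally,
$\omega = (1-s)^N$, so the per-codon selective disadvantage is

$$s \;=\; 1 - \sqrt[N]{\omega}, \qquad \omega = 1 - s_{\mathrm{total}}.$$

`per_codon_s()` and `combine_fitness()` are exact inverses of one another
(tested to $10^{-12}$), and for small totals $s \to s_{\mathrm{total}}/N$.
Two internal consistency checks of the equal-contribution and independence
assumptions are provided:

* `regress_s_vs_N()` regresses total cost on substitution count across
  alleles sharing one target codon (full gene, first half, second half).
  The wild-type point $(0, 0)$ is included by default: the unedited allele
  is a genuine zero-substitution observation, and including it is required
  to reproduce the fit statistics this package's acceptance checks assert.
  It can be dropped with `include_origin = FALSE`.
* `additivity_test()` compares the summed costs of part-alleles with the
  cost of the combined allele by a t-type contrast on summary statistics
  (root-sum-square standard errors, Welch–Satterthwaite degrees of
  freedom).

# From competition trajectories to a selective disadvantage

Serial-transfer competitions are observed as ratios of focal to reference
strain every 10 generations over 30 generations. The chain is:

1. **Slope estimation** (`estimate_s()`): the selection coefficient is the
   OLS slope of $\ln(\text{ratio})$ on generation. A two-point estimator
   (`method = "endpoints"`) is available as a robustness option; OLS over
   all four time points is the default because it uses all observations and
   is the standard estimator for log-linear competition data.
2. **Outlier filtering** (`filter_outliers()`): replicates whose slope
   deviates from the group median by more than 0.008 per generation are
   removed. The window reflects the empirical spread of clean replicate
   competitions; larger excursions indicate a secondary genetic change in
   that culture, not the fitness of the allele. The median is computed once
   on the raw group (a single pass, not an iterative re-filtering), and the
   filter is applied to raw per-group values *before* normalization,
   following the stated order of the experimental protocol.
3. **Dye-swap normalization** (`normalize_to_reference()`): each estimate is
   expressed relative to the mean wild-type-control slope of its own dye
   batch, cancelling additive marker effects; the control mean maps to 0 in
   every batch.
4. **Group comparison** (`compare_groups()`): the selective disadvantage is
   the mean difference between control and test groups (positive = cost),
   with a two-tailed t-test and the 95% CI of the difference. Welch's
   unequal-variance test is the default — the protocol statement "a
   two-tailed t-test" does not pin down the variance assumption, and Welch
   is the safer default; `var_equal = TRUE` restores the pooled test.
   Degenerate (zero-variance) groups collapse the CI with a warning rather
   than erroring, so noiseless synthetic data flow through the chain.

`normality_check()` wraps the standard Shapiro–Wilk test (delegated to
`stats::shapiro.test()`, by contract) for verifying that within-window
slopes look Gaussian.

# Codon-usage statistics

`count_codons()` tallies codons over a user-supplied set of highly
expressed genes (the classical recipe: elongation factors plus ribosomal
proteins), skipping the first 40 codons of every gene because N-terminal
codon usage is shaped by translation-initiation constraints rather than
elongation-level selection. RSCU is the observed count divided by the
equal-usage expectation; relative adaptiveness is
$w_a = \mathrm{RSCU}_{\mathrm{syn}} / \mathrm{RSCU}_{\mathrm{wt}}$, where
the wild-type reference codon of each family defaults to the
maximum-RSCU codon (in highly expressed reference sets this is the optimal
codon; it can be overridden per family). Two deliberate conventions:

* **Logarithm base.** `log_wa` is $\log_{10} w_a$. The magnitudes this
  produces for rare-versus-optimal codons in strongly biased reference sets
  match the scale of published adaptiveness tables; the natural log would
  compress the same ordering by a constant factor and would change nothing
  downstream except axis scales, since `log_wa` enters only correlations.
* **Alphabet.** Sequences are held internally as DNA; all reported codons
  use the RNA alphabet, the convention of the codon-usage literature.

# Allele design

`design_allele()` replaces, beyond a protected prefix of 40 codons, every
codon of a targeted amino acid (optionally restricted to one source codon,
e.g. only CGU→CGG) by the chosen synonymous codon, within the full gene or
a configurable sub-interval. The stop codon is never edited, protein
identity is verified on every design, and the substitution count N is
always reported from the actual diff — for real genes the number of
editable codons per half depends on the sequence, so N is never assumed.
The first/second-half boundary defaults to the midpoint of the editable
range and is explicitly configurable, because published half-gene designs
split at sequence-specific positions that cannot be inferred from counts
alone.

# Translation kinetics

The time to decode a codon is modelled as inversely proportional to the
summed concentration of the tRNA species that recognize it:
$\Delta t_{\mathrm{trans}} = 1/n_{\mathrm{syn}} - 1/n_{\mathrm{wt}}$.
Recognition sets (wobble rules) are *data*, not code: the bundled table
`inst/extdata/trna_abundance_synthetic.tsv` encodes standard bacterial
wobble pairings with synthetic concentrations of plausible rank and
magnitude, and users supply their own measurements for real analyses.
Units are reciprocal micromolar and are reported as-is; the quantity is
used only in correlations, where the absolute scale cancels.

# Anti-SD hexamer scanning

Internal Shine–Dalgarno-like hexamers can pair with the 3' tail of 16S
rRNA (anti-SD, default `CACCUCCUUA`) and stall elongating ribosomes.
`scan_anti_sd()` slides a 6-nt window at every offset — all three frames,
whole allele, including the protected prefix — and counts windows with
hybridization energy strictly below each threshold (defaults −4 and −6
kcal/mol). The energy map is generated once per anti-SD sequence by a
nearest-neighbor RNA:RNA duplex calculation (Watson–Crick and G:U stacks,
duplex initiation and terminal penalties, best contiguous helix over all
antiparallel alignments), cached, and fully deterministic. It is a
synthetic stand-in for experimentally parameterized hybridization models;
because downstream use is a count of strongly pairing windows, the ranking
of hexamers matters and the absolute calibration does not. Any externally
computed map can be passed via the `energies` argument, and a missing
hexamer fails loudly rather than silently scoring zero.

mRNA folding free energies are *consumed*, never computed: `load_ddg()`
validates an externally produced per-allele table. Signed values are
accepted as supplied, since published tables occasionally report signed
changes under an "absolute change" heading; the loader does not resolve
that discrepancy, it preserves the data.

# mRNA quantification

Rifampicin run-out qPCR series are analyzed by ΔΔCt with an assumed
amplification efficiency of 2.0 (no standard curve is modelled; the
efficiency is configurable). Technical dilutions are averaged after
dilution correction ($\mathrm{Ct} - \log_2 d$ for a $d$-fold dilution).
Half-life is $-1/\text{slope}$ of $\log_2$ relative quantity against time,
using a long-lived reference transcript (tmRNA by convention); flat or
rising series are flagged `not estimable` instead of returning a negative
half-life. Relative quantities are invariant to instrument-wide Ct offsets.

# The synthetic-data generator

`simulation_config()` fixes the study conditions the generators emulate:

| parameter | default | meaning |
|---|---|---|
| `replicates` | 12 | cultures per strain per dye orientation (24 effective with the dye swap) |
| `generations` | 0, 10, 20, 30 | sampling every 10 generations of serial transfer |
| `sigma_lnratio` | 0.025 | SD of Gaussian noise per ln-ratio observation (≈0.25%/generation on slopes) |
| `outlier_prob` | 0.02 | probability a replicate carries a persistent slope shift |
| `outlier_jump` | 0.015 | magnitude of that shift per generation (random sign) |
| `dye_effect` | 0.001 | additive slope effect of one dye orientation |
| `disadvantages` | 0 (control), 0.0072 | true per-allele costs, the scale of a fully recoded high-expression allele |
| `ct_sigma` | 0.1 | Gaussian noise per qPCR well |

The ln-ratio noise default is chosen so that essentially all clean replicate
slopes fall within the 0.8%/generation filter window of their group median
(slope SD $= 0.025/\sqrt{500} \approx 0.0011$), which is exactly the regime
in which a single-pass median filter is safe. Noise is applied to ln-ratio
observations, not to marker counts — competition data are consumed as
ratios — and outliers are persistent slope shifts, emulating a secondary
genetic change rather than a bad measurement. Gene sets are drawn
codon-wise from per-family probability vectors (default: 75% of the mass on
one optimal codon per family), which guarantees in-frame, stop-free genes
with strong, known bias.

What the generator deliberately does **not** emulate: flow-cytometer count
noise (a binomial count layer would add realism but the analysis consumes
ratios), autocorrelated drift within a competition, position-dependent
fitness effects of individual codons, and reference-gene instability in
qPCR. Passing the recovery tests therefore demonstrates that the chain is
correct and well calibrated under its own assumptions — not that those
assumptions hold for any particular real data set.

# Verification strategy and problem sizes

Every operation is tested against an independent oracle (brute-force
tallies, exhaustive window enumeration, closed-form arithmetic, Monte-Carlo
recovery), and the pipeline is verified end to end: with the default
configuration, across 1,000 simulated studies, the 95% CI for the
per-allele disadvantage covers the truth at 93–97%, the median filter
removes ≥90% of injected outlier replicates and <2% of clean ones. These
sizes (1,000 seeds; 24 effective replicates; genes of 100–300 codons) were
chosen as the smallest at which the binomial uncertainty of a coverage
estimate is well inside the asserted band.

# Known limitations

* The per-codon decomposition inherits the equal-contribution and
  independence assumptions; both are testable with the provided tools but
  not enforceable.
* The bundled tRNA table and hexamer energy model are synthetic stand-ins
  with the right schema and structure; conclusions about real organisms
  require measured tRNA concentrations and a calibrated hybridization
  model.
* `log_wa` of an unobserved codon in a used family is $-\infty$; such
  codons should be excluded from correlations by the caller.
* The ΔΔCt model assumes perfect efficiency 2.0 for all amplicons;
  efficiency differences between target and reference bias half-lives.
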