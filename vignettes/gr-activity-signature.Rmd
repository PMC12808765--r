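---
title: "Deriving and evaluating a GR activity signature"
author: "GRsig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating a GR activity signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GRsig)
library(SummarizedExperiment)
```

# The problem

Activating the glucocorticoid receptor (GR, *NR3C1*) with dexamethasone
(Dex) represses estrogen-receptor (ER) signaling in ER+ breast cancer
models. Because GR *expression* is a poor proxy for GR *activity*, the
analysis this package implements summarizes activity as a gene
signature: the genes most strongly and most rapidly induced by Dex,
shared between two independent cell-line models. That signature can then
score any expression profile — including patient tumors with survival
follow-up — and its prognostic value can be tested.

`GRsig` implements the derivation, the clinical evaluation, and the
companion analyses (ChIP-seq peak-to-gene assignment, pre-ranked
enrichment, TMT proteomics, drug-combination synergy), together with a
synthetic-data generator that plants known truth in every input.

# Signature derivation

The pipeline (`deriveSignature()`) runs, in order:

1. **Low-expression filtering** (`filterLowExpressed`): keep genes with
   CPM >= 1 in at least `min_samples` samples, where `min_samples`
   defaults to the smallest design group (3 at the default
   2 models x 2 treatments x 2 timepoints x 3 replicates design). The
   original analysis used edgeR's `filterByExpr`, whose effective
   parameters depend on the data; the explicit CPM rule is a fixed,
   testable equivalent.
2. **TMM normalization** (`tmmFactors`): the trimmed-mean-of-M-values
   factor, implemented from its published definition (75th-percentile
   reference selection, 30% M-trim, 5% A-trim, precision weighting by
   the delta-method binomial variance, geometric-mean-1 rescaling). The
   test suite checks agreement with edgeR's implementation to 1e-6.
3. **logCPM** (`logCPM`): `log2((y + c) / (eff.libsize + 2c) * 1e6)`
   with pseudo-count `c = 0.5`. The `2c` in the denominator keeps the
   transform exact for the all-zero gene; both conventions are
   configurable.
4. **Differential expression** (`deTest`): per model and timepoint, Dex
   vs vehicle on logCPM. `logFC` is the difference of group means. The
   default p-value is an empirical-Bayes moderated t with a
   mean-variance trend (limma-trend). With triplicates an unmoderated
   Welch t has ~4 residual degrees of freedom; its per-gene variance
   estimates are too unstable to rank genes reliably at stringent FDR
   cutoffs, and variance moderation is also what the original
   quasi-likelihood analysis does in spirit. `method = "welch"` is
   retained for the unmoderated test; zero-variance, zero-logFC genes
   get p = 1 in either mode.
5. **Shared-effect selection** (`sharedEffectGenes`): genes with
   |log2FC| > 2 and FDR < 0.01 (both strict) in *both* models at 24 h.
   Sign concordance is required by default: a gene significant up in one
   model and down in the other does not share an effect. Selection
   without concordance is a defensible alternative reading;
   `sign_concordant = FALSE` provides it.
6. **Mean-centering and k-means** (`meanCenter`, `kmeansCluster`): rows
   centered over all 24 samples, Lloyd iterations with k-means++
   initialization, k = 4, 50 restarts keeping the lowest inertia,
   at most 300 iterations, all seeded. Cluster labels are arbitrary;
   nothing downstream depends on them.
7. **Onset selection** (`onsetScore`, `selectSignature`): for each
   cluster, the mean over its genes of (mean logCPM in Dex 8 h samples,
   both models) minus (mean logCPM in vehicle samples). The signature is
   the argmax cluster and must have positive onset — the signature is
   Dex-*induced* by construction. The control baseline is all
   vehicle samples at both timepoints (`control_scope = "all_vehicle"`);
   restricting to vehicle 8 h only is available as an option. Ties break by the larger
   Dex 24 h minus vehicle difference, then by the smaller label.

Containment holds by construction: signature genes ⊆ shared-effect
genes ⊆ filtered universe, and the pipeline is deterministic given its
seed.

```{r derive}
se  <- simulateCounts(simCountConfig(seed = 1))
sig <- deriveSignature(se, signatureParams(seed = 1))
sig
```

# What the generator emulates — and what it does not

`simulateCounts()` draws negative-binomial counts
(`Var = mu + phi * mu^2`, shared dispersion `phi = 0.1` by default) for
the 2-model x {vehicle, Dex} x {8 h, 24 h} x 3-replicate design, i.e. 12
samples per model. Four gene classes are planted: `early_up` and
`early_down` respond at both timepoints, `late_up`/`late_down` only at
24 h, with |log2FC| = 3 by default and a per-model N(0, 0.1) jitter so
the two models share an effect without being identical — that jitter is
what makes the both-models intersection rule non-trivial. Baseline
expression is log-normal (`meanlog = log(200)`, `sdlog = 1`), library
sizes uniform in 1.5–2.5 million, and each sample's expected total
equals its drawn library size. Defaults (5,000 genes, 60 genes per
class) keep derivation times in seconds while leaving enough null genes
for FDR behaviour to matter; these sizes are this package's choice of a
desk-scale study, as the original data's distributional parameters are
not published.

`simulateCohort()` plants survival: per-patient expression around
per-gene baselines, activity score = total log-expression over the
signature genes, event times exponential with hazard
`h0 * exp(beta * z)` on the standardized score (`beta = -0.8`,
protective, by default), administrative censoring at 120 months with
`h0` solved so ~60% of patients have events, and an `ESR1` gene
anti-correlated with the score (`alpha - gamma * z + noise`) — the
synthetic analogue of ER loss under GR activity.

`simulateGenomePeaks()` builds toy chromosomes with spaced genes (TSSs
at least 12 kb apart so basal domains stay disjoint and the planted
gene-to-peak truth is exact), gives a configurable fraction of genes a
GR peak inside the basal window, keeps background peaks away from all
gene neighborhoods, overlaps a fraction of GR peaks with ER peaks, and
retains a fixed fraction of ER 1 h peaks at 24 h — a qualitative
emulation of the post-Dex loss of ER binding.

What the generator deliberately does **not** model: batch effects,
read-level artifacts, gene length and GC bias, correlated genes,
informative censoring, isotope-impurity leakage between TMT channels,
and peak-shape signal. Passing tests therefore demonstrate that the
*algorithms* recover what was planted under their stated model — not
that the model captures every property of real data.

# Clinical evaluation

Scores are summed log-expression over signature genes
(`scoreSamples`), tolerating up to 50% missing genes with a warning —
cross-platform application implies partial overlap. Stratification
(`stratifyQuartiles`) uses type-7 quantiles (R's default linear
interpolation — a concrete, testable convention) with inclusive
boundaries: Low = score <= Q1, High = score >= Q3. If Q1 = Q3 the vector
is degenerate and everyone becomes Intermediate, with a warning, rather
than an arbitrary split. Survival uses `survival::survfit` /
`survdiff` / `coxph` (Breslow ties — the simplest standard choice, and
tie-free synthetic data makes the Efron/Breslow distinction moot);
independent hand-coded product-limit computations back the tests.

For the cross-stratum *ESR1* comparison the package uses an
independent-sample Wilcoxon rank-sum test: the High and Low strata are
disjoint patient groups, so a matched-pairs signed-rank test has no
natural pairing and is not offered.

# Cistrome analysis

Coordinates follow the BED convention (0-based half-open) at the file
boundary and standard 1-based `GRanges` in memory. Peaks on chrM/chrX/
chrY or overlapping a blacklist interval by >= 1 bp are dropped;
enrichment filtering keeps peaks with log2 enrichment strictly above 2
in at least one sample. Regulatory domains are basal-plus-extension:
5 kb upstream / 1 kb downstream of the TSS, strand-oriented, each edge
extended outward up to `distal_limit` but never into a neighboring basal
domain, contested gaps split at the midpoint between basal edges (so
domains can only overlap within basal windows). `distal_limit` defaults
to 1,000 bp, matching the proximal-scale settings this analysis style
uses (5 kb up, 1 kb down, distal up to 1 kb); since GREAT's conventional
distal default is megabase-scale, the parameter is explicit and required
knowledge for any real-genome use.
Peak-to-gene assignment uses the peak midpoint
(`floor((start + end) / 2)` in BED coordinates) — a single deterministic
rule; any-overlap assignment is available as an option.

# Pre-ranked enrichment

Genes are ranked by logFC (ties broken by gene id). The running sum
increments by `|r|^p / N_R` at set hits (p = 1 by default, p = 0 for the
unweighted statistic) and decrements by `1/(N - N_hits)` at misses; the
enrichment score is the signed extremum, the leading edge the hits up to
(or from) it. The null permutes gene labels — matched-size random sets,
shared across sets of equal size — because in pre-ranked
GSEA sample permutation is unavailable. P-values are
sign-stratified with the +1 correction, so the minimum attainable
p-value is `1/(1 + #same-sign permutations)`; NES divides ES by the mean
|same-sign permutation ES|. Fixed-count permutation (default 1,000) is
used rather than adaptive refinement; p-values below the permutation
floor are reported at the floor.

# Proteomics and synergy

TMT processing equalizes channel totals (each channel scaled by the mean
total over its total — exactly preserving within-channel ratios), sums
PSM intensities per protein and channel, tests `log2(x + 1)` intensities
between channel groups with the same moderated t machinery as the RNA
side, and thresholds at |log2FC| > 0.5, FDR < 0.05 (strict). Reporter
isotope-impurity adjustment is upstream of this package's scope.
RNA-protein concordance is the Pearson correlation of logFC over
inner-joined gene symbols.

Synergy uses the combination index `CI = (AB * C) / (A * B)`; a pair is
synergistic iff `CI < 1 - epsilon` with `epsilon = 0` (the inequality is strict). Replicates are averaged per arm
before the test — the mean is the least surprising default — with a seeded
bootstrap interval available for uncertainty.

```{r synergy}
plate <- simulateViability(simViabilityConfig(sigma = 0.3, seed = 1))$plate
synergyTable(plate)[c("combination_index", "is_synergistic")]
```

# Numerical choices and degenerate inputs

* All randomness flows from one integer seed through named substreams,
  so partial pipelines reproduce exactly and generators do not disturb
  the caller's RNG state.
* Strict inequalities everywhere a threshold is stated (logFC, FDR,
  enrichment, CI): boundary values are excluded, and tests pin the
  boundaries.
* k-means with fewer distinct rows than clusters collapses duplicates
  onto identical centers with zero inertia instead of failing; empty
  clusters during a restart simply discard that restart.
* Zero-variance genes in `deTest` get p = 1 (no evidence), not NaN.
* An all-zero sample is an error naming the sample; a zero-total TMT
  channel likewise.
* `bhAdjust` validates p in [0, 1] and delegates to the standard step-up
  implementation; tests compare against a brute-force step-up oracle.

# Problem sizes used in the test suite

The bundled tests and the acceptance script run at desk scale: 5,000
gene x 24 sample count simulations (ten seeds for recovery medians),
2,000-gene null calibrations, 800-patient cohorts (200 simulations for
Cox coverage; 1,000 simulations of 200 patients for log-rank type-I
error), 100 random toy genomes for interval-oracle comparisons, and
200-plate synergy batches. These sizes give stable Monte-Carlo estimates
for the properties checked while keeping a full run in a few minutes.

# Known limitations

* The exact published 52-gene signature is not reproducible here: it
  requires the original raw sequencing data and tool versions. The
  package reproduces the *procedure* and validates it on planted truth.
* The moderated-t DE test is a deliberate, documented divergence from
  the original edgeR quasi-likelihood fit; effect-size estimates agree
  but per-gene p-values need not.
* The GSEA null is gene-permutation only; no multilevel p-value
  refinement below the permutation floor.
* Real-genome regulatory-domain analysis should revisit `distal_limit`
  (see above) and supply a real blacklist.
* The cohort generator plants a linear log-hazard; non-proportional
  hazards and clinical covariates are out of scope.
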