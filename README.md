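# GRsig

Glucocorticoid receptor (GR) activation by dexamethasone (Dex) can silence
estrogen-receptor (ER) signaling in ER+ breast cancer. A practical way to
study this clinically is a **GR activity gene signature**: a set of genes
switched on early after Dex, derived from time-course RNA-seq in two
cell-line models, then used to score and stratify patient tumors.

`GRsig` implements that analysis as a tested, self-contained R pipeline:

* **Signature derivation** — TMM normalization and logCPM, per-model
  Dex-vs-vehicle differential expression at 8 h and 24 h, selection of
  genes with a strong *shared* effect in both models at 24 h
  (|log2FC| > 2, FDR < 0.01, concordant sign), k-means (k = 4) on
  mean-centered logCPM, and selection of the cluster with the strongest
  *expression onset* (Dex 8 h minus vehicle controls).
* **Clinical evaluation** — signature scoring by total log-expression,
  quartile stratification (High / Intermediate / Low), Kaplan–Meier
  curves, log-rank tests, univariate Cox proportional hazards, and
  cross-stratum comparison of a designated gene (e.g. *ESR1*).
* **Cistrome analysis** — peak filtering (chrM/chrX/chrY, blacklist,
  log-enrichment > 2), ER/GR co-binding classes, GREAT-style
  basal-plus-extension regulatory domains (5 kb up, 1 kb down, bounded
  distal extension), midpoint peak-to-gene assignment, and gene-set peak
  proximity fractions.
* **Pre-ranked enrichment** — weighted Kolmogorov–Smirnov-like running
  sum over a logFC ranking, gene-permutation null, sign-stratified
  p-values, NES, BH correction.
* **TMT proteomics** — channel-total equalization, PSM-to-protein rollup,
  differential abundance (|log2FC| > 0.5, FDR < 0.05), and RNA–protein
  logFC concordance (Pearson).
* **Drug synergy** — the combination-index inequality
  `AB/C < (A/C)(B/C)` on viability plates.
* **Synthetic data** — every input above can be generated with planted
  ground truth (`simulateCounts`, `simulateCohort`,
  `simulateGenomePeaks`, `simulateReporter`, `simulateViability`), so the
  full pipeline is testable without any external download.

## The core model

Counts are modeled negative-binomially, `Var = mu + phi * mu^2`.
Normalization uses trimmed-mean-of-M-values factors `f_s` (geometric mean
1), and

```
logCPM[g,s] = log2( (y[g,s] + c) / (N_s * f_s + 2c) * 1e6 ),  c = 0.5
```

The signature is the argmax-onset k-means cluster among shared-effect
genes, where onset is the mean over cluster genes of (mean logCPM in Dex
8 h samples − mean logCPM in vehicle samples). Patients are scored by
`score_p = sum_{g in signature} x[g,p]` and stratified by type-7
quartiles; survival uses the product-limit estimator, the Mantel–Cox
log-rank test, and a Breslow-ties Cox fit with hazard
`h(t) = h0(t) * exp(beta * z)`.

## Worked example

```r
library(GRsig)

se  <- simulateCounts(simCountConfig(seed = 1))   # 5000 genes x 24 samples
sig <- deriveSignature(se, signatureParams(seed = 1))
sig
#> GRSignature with 60 genes
#>   selected cluster: 3 (onset score 3.004)
#>   cluster onset scores: -0.037, 0.028, 3.004, -3.040
#>   derivation funnel: genes=5000 -> filtered=5000 -> shared_effect=238 -> signature=60
```

The funnel mirrors the analysis design: 5,000 simulated genes, 238 with a
strong shared Dex effect in both models at 24 h, and a 60-gene early-onset
cluster (the generator planted 60 `early_up` genes; the onset score of
the selected cluster, +3.0 log2 units, is the planted effect size).

Scoring and survival on a simulated cohort with a planted protective
hazard (beta = −0.8 per SD of the signature score):

```r
ch     <- simulateCohort(simCohortConfig(seed = 1))
scores <- scoreSamples(cohortExpr(ch$cohort), sprintf("sig%02d", 1:52))
st     <- stratifyQuartiles(scores)
table(st$stratum)
#>          Low Intermediate         High
#>          200          400          200

coxFit(survivalTime(ch$cohort), eventStatus(ch$cohort),
       as.numeric(scale(scores)))
#> beta -0.857, HR 0.424 (95% CI 0.385-0.468)

logrankTest(survivalTime(ch$cohort), eventStatus(ch$cohort), st$stratum)
#> chisq 260.06 on 2 df, p ~ 0
```

High signature scores carry a hazard ratio well below 1 — the high-GR-
activity stratum survives longer — and *ESR1* expression falls with the
score (`compareExpressionAcrossStrata`), the planted anti-correlation.

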