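---
title: "Phospho-anchored transcriptional signatures: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phospho-anchored transcriptional signatures: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphosig)
```

## What the package computes

`phosphosig` links two measurement layers of the PI3K/AKT/mTOR axis.
At the protein layer, reverse-phase protein arrays (RPPA) quantify
phospho-specific antibodies; a pathway's **activity score** is the sum
of its antibodies' normalized levels per sample. At the transcript
layer, a **phospho-anchored signature** is a pair of gene sets — genes
up- or down-modulated in samples with high anchor phosphorylation —
derived on a cohort that has both layers, and then usable on cohorts
that have expression only. A cohort is scored per sample by the
ratio-of-means statistic

\[
\mathrm{score1}_s = \frac{\mu^{UP}_s}{\mu^{DW}_s}, \qquad
\mathrm{final}_s = \frac{\mathrm{score1}_s - \overline{\mathrm{score1}}}{\mathrm{sd}_{pop}(\mathrm{score1})},
\]

where \(\mu^{UP}_s\) and \(\mu^{DW}_s\) are the mean expression of the
up and down sets in sample \(s\) and the z-scaling is done within the
cohort being scored. Final scores are then compared between clinical
strata (BMI class, inferred menopause) with two-sided Wilcoxon
rank-sum tests.

## The derivation model and its assumptions

Derivation dichotomizes the anchor antibody at a quantile cut
(`q = 0.5` by default) into phospho-high and phospho-low classes. Three
assumptions are implicit and worth stating:

1. **Monotone coupling.** Genes responsive to the anchored phospho
   state shift their mean log2 expression monotonically with it; a
   two-class location test plus a correlation filter then suffices to
   find them.
2. **Independent filters agree in sign.** A real signature gene must
   be both differentially expressed between the classes *and*
   correlated with the continuous anchor, with consistent sign. Genes
   passing both filters with opposite signs are treated as artifacts
   ("discordant") and excluded — the count is kept in the signature's
   provenance so the user can see how often it happens.
3. **Non-negative scoring scale.** The ratio μUP/μDW is meaningful
   only when expression values are non-negative; on a signed scale
   (e.g. mean-centred log intensities) the denominator can vanish or
   flip sign. Counts are therefore transformed to
   `log2(CPM + 1)` before scoring, and scoring refuses matrices with
   negative entries or a denominator below `eps = 1e-8`.

### Differential-expression engine

The high-vs-low test is a per-gene Welch two-sample t-test on log2
values with Benjamini–Hochberg adjustment across all tested genes.
A count-model fit (negative-binomial regression) would also be
defensible; the Welch test was chosen because it is deterministic,
assumption-light at the ~100-samples-per-class sizes this design
targets, and exactly reproducible against a closed-form oracle in the
test suite. Genes with zero variance in both classes get `p = 1` and a
`zero_variance` flag rather than `NaN`. The derivation contract is the
resulting gene sets, not the engine; `differential_expression()` is a
self-contained stage that can be swapped.

### Correlation filter

`mrna_phospho_correlation()` defaults to Spearman: RNA-seq log-CPM and
RPPA intensities live on unrelated scales, and rank correlation is
invariant to any monotone mismatch between them. P-values use the
t-transform of r on n − 2 degrees of freedom (applied to
rank-transformed data in the Spearman case). For the cohort sizes the
package targets (n ≥ 100 shared samples) this approximation is
indistinguishable from the exact permutation null; at very small n the
Pearson option with its exact t reference is preferable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 0.5 | anchor quantile for the high/low split; the data give no natural cut, and the median maximizes class balance |
| `lfc_min` | 1 | minimum abs. log2 fold change (2-fold) for signature membership |
| `fdr_max` | 0.05 | BH-adjusted DE threshold |
| `p_max` | 0.05 | correlation-filter p threshold |
| `min_coverage` | 0.5 | fraction of each gene set that must be present in a scored matrix; cross-platform scoring (arrays vs RNA-seq) routinely loses genes |
| `eps` | 1e-8 | smallest admissible μDW |
| `missing_policy` | strict | absent pathway antibodies are an error by default, because silently dropping one changes what the activity sum means |

Thresholds are deliberately explicit arguments rather than hidden
constants: tightening any of them can only shrink the gene sets
(a monotonicity property the test suite checks).

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates the joint structure the analysis
assumes. Per sample \(i\), a latent phospho activity
\(a_i \sim N(\delta_i, \sigma_a)\) with \(\delta_i =
\texttt{delta\_group}\cdot\sigma_a\) for obese samples and 0
otherwise. The RPPA matrix carries the five AKT-pathway antibodies,
each equal to \(a_i\) plus independent \(N(0,
\texttt{rppa\_noise\_sd})\) noise — `AKT_pS473` is the designated
anchor — plus pure-noise decoy antibodies that exercise
irrelevant-antibody handling. Planted genes shift their log2 mean by
\(\pm\beta a_i\); baselines are log-normal (SD 1.5 on the log2 scale,
a realistic RNA-seq dynamic range); counts are negative-binomial with
per-sample means rescaled to the expected library size (Poisson when
`dispersion = 0`). BMI is uniform within each class interval
([18.5, 25), [25, 30), [30, 45]) and age uniform within the pre-
(30–48) and postmenopausal (49–75) ranges, each sample premenopausal
with probability `frac_pre = 0.5`; group sizes are deterministic
rounded counts so that, e.g., 90 samples at 1/3 fractions give exactly
30 per class.

Default condition sizes — 200 samples, 2000 genes, 50 up + 50 down
planted, \(\beta = 1\), \(\sigma_a = 1\), `delta_group = 1`,
`rppa_noise_sd = 0.2`, library size 10⁶, dispersion 0.1 — are the
package's reference study design: large enough that recovery,
calibration and power are informative, small enough that the full
validation suite runs on a laptop. The power study uses 90 samples
(30 per BMI class) and 500 genes per replicate across 100 replicates.

The generator intentionally omits batch effects, tumor purity,
array-probe structure, sample-to-sample library-size biology beyond
the compositional rescaling, and any direct BMI→expression path (BMI
affects expression only through the latent activity). Passing
recovery tests on these cohorts therefore demonstrates that the
pipeline's statistics do what they claim under the stated generative
model — not that real tissue cohorts satisfy that model.

## Numerical and procedural choices

- **Quantile normalization** maps every column to the means of the
  column-sorted matrix; within-column ties receive the mean of the
  tied positions' sorted-row means. The operation is idempotent and
  sample-permutation equivariant.
- **Probe collapsing** keeps, per gene, the probe with the largest
  across-sample IQR (Q3 − Q1, linear-interpolation quantiles); IQR
  ties break to the lexicographically smallest probe id, making the
  result order-independent.
- **z-scaling** uses the population (divide-by-n) SD. Sample SD would
  differ by a constant factor only; one convention is fixed and
  documented.
- **Wilcoxon tests** are exact for combined group sizes ≤ 20 without
  ties (verified against exhaustive enumeration of all labelings),
  and otherwise use the normal approximation with continuity and tie
  correction. Pairwise BMI-class comparisons are BH-adjusted by
  default (`p_adjust = "none"` disables this).
- **Boundaries.** BMI 25 is overweight, 30 is obese (half-open
  intervals); age exactly 49 is postmenopausal. Boundary behaviour is
  pinned by tests at 25 − 1e-9, 25, 30 − 1e-9, 30.
- **Degenerate inputs** fail loudly with classed errors: a
  constant anchor cannot be stratified; a constant score vector
  cannot be z-scaled; an empty up or down set aborts assembly (with
  the nearest-miss threshold reported) unless `allow_empty = TRUE`,
  which exists for null-calibration studies where empty sets are the
  expected outcome.
- **Determinism.** All simulation randomness flows from the single
  `seed` in `cohort_config()`, applied via a scoped RNG so the
  caller's random stream is untouched; the downstream stages are
  deterministic, making the whole simulate → derive → score → compare
  pipeline byte-reproducible.
- **Text round-trips.** TSV writers format doubles with 17
  significant digits and the readers parse via strtod, so write → read
  is bit-exact.

## Known limitations

- The anchor is a single antibody; multi-antibody anchoring (e.g.
  pooling Akt pS473 and pT308 into one latent estimate) is not
  attempted — each anchor yields its own signature.
- The Welch engine assumes log-scale expression is approximately
  location-testable; extremely low counts with tiny cohorts would
  favour an exact count model instead.
- `score1` is undefined for signatures whose down set is entirely
  unexpressed in a cohort; the coverage and denominator guards make
  this an error rather than a silent number.
- Signature transfer across platforms is only as good as gene-id
  harmonization; `collapse_probes()` handles probe-level arrays, but
  id mapping itself is the user's responsibility.
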