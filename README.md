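# phosphosig

Phospho-anchored transcriptional signatures from paired expression and
RPPA data.

## The problem

Reverse-phase protein arrays (RPPA) measure phospho-protein levels —
for example Akt phosphorylated at Ser 473 — but most public cohorts
carry only gene expression. `phosphosig` bridges the two: on a cohort
with *paired* RNA-seq and RPPA data it derives a transcriptional
signature that mirrors the phosphorylation state of an anchor
phospho-protein, and that signature can then score expression-only
cohorts, so pathway activation can be compared across clinical strata
(body-mass-index classes, inferred menopausal status) where no protein
data exist. The package is aimed at analysts studying the PI3K/AKT/mTOR
axis in breast tissue, but every anchor, pathway and threshold is
configurable.

## The method

**Pathway activity (protein level).** For a pathway defined as a set of
phospho antibodies *P*, the per-sample activity score is the plain sum
of normalized phospho-protein levels, `A_s = Σ_{a ∈ P} x_{as}`.
Built-ins: the AKT set (Akt pS473, Akt pT308, GSK3 pS9, GSK3 pS21/S9,
PRAS40 pT246) and the mTOR set (AKT ∪ {mTOR, 4EBP1 pS65/pT37-T46/pT70,
RICTOR pT3135, S6 pS235-S236/pS240-S244}).

**Signature derivation.** Samples are split into phospho-high and
phospho-low classes at a quantile of the anchor antibody (median by
default). Per gene, a Welch t-test on log2 expression gives a fold
change and BH-adjusted p; genes must also correlate with the anchor
(Spearman by default, p ≤ 0.05) in the direction of their fold change:

- up set: `log2FC ≥ 1`, `FDR ≤ 0.05`, `r > 0`, `p_corr ≤ 0.05`
- down set: `log2FC ≤ −1`, `FDR ≤ 0.05`, `r < 0`, `p_corr ≤ 0.05`

Sign-discordant genes are excluded and counted.

**Signature scoring.** Per sample, μUP and μDW are the mean expression
of the up and down sets (counts are log2-CPM(+1) transformed first, so
values are non-negative), `score1 = μUP / μDW`, and the **final score**
is the z-scaling of score1 across the cohort being scored (population
SD). Group differences between BMI classes (normal-weight < 25,
overweight [25, 30), obese ≥ 30 kg/m²; menopause inferred as
premenopausal when age < 49) are tested with two-sided Wilcoxon
rank-sum tests, BH-adjusted across the pairwise family.

**Validation by simulation.** Because derivation needs paired data, the
package ships a generator: a latent per-sample phospho activity drives
both the RPPA antibodies (plus pure-noise decoys) and planted up/down
gene sets in a negative-binomial count matrix, with a latent shift for
the obese group. The planted truth makes recovery, calibration and
power measurable end to end.

## Worked example

```r
library(phosphosig)

cohort <- simulate_cohort(cohort_config(n_samples = 200, n_genes = 2000,
                                        n_up = 50, n_down = 50,
                                        beta = 1, seed = 11))
sig <- derive_signature(cohort$expression, cohort$rppa, "AKT_pS473")
sig
#> <gene_signature> AKT_pS473_SIGNATURE (anchor: AKT_pS473)
#>   up: 50 genes, down: 50 genes, discordant excluded: 0
#>   thresholds: |log2FC| >= 1, FDR <= 0.05, corr p <= 0.05

scores <- score_cohort(cohort$expression, sig)
head(scores, 3)
#> # A tibble: 3 × 5
#>   sample_id mu_up mu_down score1 final_score
#>   <chr>     <dbl>   <dbl>  <dbl>       <dbl>
#> 1 S0001      8.67    7.62  1.14      -0.0279
#> 2 S0002      9.23    7.14  1.29       0.483
#> 3 S0003      7.84    8.60  0.912     -0.771

cor(scores$final_score, cohort$truth$samples$latent_activity,
    method = "spearman")
#> [1] 0.9982855

cmp <- compare_groups(scores, assign_groups(cohort$clinical))
dplyr::select(cmp, group1, group2, n1, n2, p.value, p.adj, direction)
#> # A tibble: 3 × 7
#>   group1        group2        n1    n2   p.value     p.adj direction
#> 1 normal-weight overweight    66    67 0.862     0.862     normal-weight < over…
#> 2 normal-weight obese         66    67 0.0000178 0.0000268 normal-weight < obese
#> 3 overweight    obese         67    67 0.0000179 0.0000268 overweight < obese
```

Reading the output: the derived signature recovers exactly the 50
planted up and 50 planted down genes; each sample's `score1` is the
ratio of its mean up-gene to mean down-gene log-CPM and `final_score`
its z-value within the cohort; the final score tracks the simulated
latent phospho activity nearly perfectly (Spearman ρ ≈ 0.998); and the
obese group — whose latent activity was shifted by one standard
deviation — scores significantly higher than both other BMI classes,
while normal-weight and overweight (no shift) do not differ.

The derived signature can be exported and applied to any other
expression cohort:

```r
write_gmt(signature_to_gmt(sig), "akt_ps473_signature.gmt")
other <- read_expression("other_cohort.tsv", scale = "counts")
other_scores <- score_cohort(other, sig)
```

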