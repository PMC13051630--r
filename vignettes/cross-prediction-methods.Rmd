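---
title: "Predicting F1 hybrid performance from parental data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting F1 hybrid performance from parental data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In self-pollinating crops such as chili pepper (*Capsicum annuum*),
breeding programs cross highly homozygous inbred lines and select among
the F1 progeny. Phenotyping every candidate cross is expensive —
capsaicinoid content in particular requires HPLC chemistry on harvested
fruit — so the practical question is whether the phenotype of an
untested F1 can be predicted from *parental information alone*: the
parents' genotypes and their multi-year phenotype records. crossgp
implements that workflow end to end, together with the heterosis
analysis needed to understand when and why such predictions fail.

The workflow has three stages:

A. **Phenotype summarization.** Multi-year records are reduced to one
   value per accession by a mixed model; broad-sense heritability is
   estimated per trait.
B. **F1 genotype estimation.** An F1's marker genotype is estimated
   deterministically from its parents' genotypes.
C. **Genomic prediction.** Models trained on the inbred panel only are
   applied to the estimated F1 genotypes; accuracy and per-individual
   error are then related back to heterosis.

A synthetic-data module generates inbred panels, crosses and phenotypes
with the statistical structure this analysis assumes, so every stage is
testable without access to field data.

# Models and procedures

## Phenotype BLUPs and heritability

For each trait the model is

$$ y_{iy} = \beta_y + u_i + e_{iy}, \qquad
   u_i \sim N(0, \sigma_g^2), \quad e_{iy} \sim N(0, \sigma_\varepsilon^2), $$

with year $y$ fixed and accession $i$ random, fitted by REML (`fit_blup`,
backed by lme4). The reported BLUP is the unweighted mean of the year
effects plus the shrunken accession effect, so it lives on the trait
scale and heterosis percentages do not depend on year coding. On a
balanced design this reduces to the classical shrinkage form
$\hat\mu + \frac{\sigma_g^2}{\sigma_g^2 + \sigma_\varepsilon^2/n}(\bar
y_i - \hat\mu)$, which the test suite uses as an independent oracle.
Broad-sense heritability on the accession-mean basis is

$$ h_b^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_\varepsilon^2 / n}
   \times 100, $$

with $n$ the number of replicate years. Derived traits (total content,
per-fruit contents) are computed on the yearly records first and each
derived trait is then BLUPed independently.

## Heterosis statistics

With $P_{F1}$, $P_{P1}$, $P_{P2}$ the BLUPs of an F1 and its parents,
$P_{mid} = (P_{P1}+P_{P2})/2$ and $P_{max} = \max(P_{P1}, P_{P2})$:

$$ \mathrm{MP}\,(\%) = \frac{P_{F1}-P_{mid}}{P_{mid}} \times 100, \qquad
   \mathrm{HP}\,(\%) = \frac{P_{F1}-P_{max}}{P_{max}} \times 100. $$

F1s are classified as *non* (MP < 0), *medium* (MP > 0 and HP < 0) or
*strong* (HP > 0) heterosis. The defining inequalities are strict;
boundary ties (probability zero on continuous data) go to the less
extreme group — MP = 0 is non, HP = 0 is medium. Percent heterosis is
meaningless with a non-positive denominator, so such records are flagged
`NA` with a reported count and excluded from summaries; how a field
dataset should handle them is a genuinely open question and the package
deliberately refuses to guess. The additive effect of a cross is
$|P_{P1}-P_{P2}|/2$ and parental genetic distance is the Euclidean
distance between the parents' $\{-1,0,1\}$ genotype vectors.

## F1 genotype estimation

The estimated F1 genotype is the parental mean,
$g_{F1} = (g_{P1}+g_{P2})/2$, with the fractions $\pm 0.5$ that arise
from a heterozygous parent adjusted to $\pm 1$, keeping all codes in
$\{-1,0,1\}$. Segregation at heterozygous parental loci is *not*
modelled: the estimate is deterministic given the parents. On a panel of
near-homozygous inbreds this is exact at almost all loci; the synthetic
module's true-genotype simulator quantifies the residual discrepancy,
which is confined to loci where a parent is heterozygous.

## The model menu

Eleven predictors share one fit/predict interface (`fit_gp_model`):

* **ridge / lasso / en** — coordinate-descent elastic net on
  standardized markers (glmnet), mixing parameter 0 / 1 / 0.5; penalty
  chosen by seeded 5-fold cross-validation minimizing MSE. The paper
  behind this package does not state the CV scheme or whether markers
  were standardized, so these are explicit configuration, not inferred
  intent.
* **brr / bayes_a / bayes_b / bayes_c** — Gibbs samplers (implemented in
  C++ for speed) with standard conjugate updates: a common
  scaled-inverse-$\chi^2$ marker variance (BRR), per-marker variances
  (Bayes A), and spike-and-slab inclusion with sampled $\pi$ (Bayes B:
  per-marker slab variances; Bayes C: common slab). Defaults: 6,000
  iterations, 1,000 burn-in, $\nu = 4$, hyperprior scales from the usual
  variance-partition heuristic assigning half the phenotypic variance to
  markers, $\pi \sim \mathrm{Beta}(1, 9)$ started at 0.1. Two sampler
  limits anchor correctness: BRR posterior-mean predictions track
  closed-form ridge at the prior-matched penalty, and Bayes C with
  $\pi$ fixed at 1 collapses onto BRR.
* **gblup_a / gblup_ad / gblup_gauss** — kernel GBLUP. The additive
  kernel is VanRaden-style, $K = WW'/(2\sum_j p_j(1-p_j))$ with codes
  centered by $2(p_j - 0.5)$; the dominance kernel uses the
  heterozygosity design centered by $2p_j(1-p_j)$; the Gaussian kernel
  is $K_{ij} = \exp(-D_{ij}^2/\theta)$ on Euclidean code distances.
  Single-kernel REML profiles the variance ratio through one
  eigendecomposition (a bounded search of $\log\lambda$ over
  $[-12, 12]$, tolerance 1e-8); the two-kernel additive + dominance fit
  maximizes the restricted likelihood over both ratios with L-BFGS-B and
  random restarts, components clamped nonnegative. Prediction follows
  the standard kernel-BLUP extension
  $\hat\mu + K_\times (K + \delta I)^{-1}(y - \hat\mu)$.
* **rf** — bagged regression trees (ranger, single-threaded and seeded),
  500 trees, mtry $= p/3$.

Two frozen-at-training rules matter for correctness: allele frequencies
for kernel centering come from the training (inbred) panel only and are
reused when building F1 cross-kernels, and the Gaussian bandwidth is the
median nonzero squared training distance, fixed before any F1 is seen.
The median heuristic is scale-free and standard where no bandwidth is
prescribed.

## Error-factor analysis

Per F1, the root square error is
$\mathrm{RSE} = \sqrt{(y_{obs}-y_{pred})^2} = |y_{obs}-y_{pred}|$. Per
trait, RSE is correlated (Pearson, two-sided t test, df $= n-2$) with
the additive effect, |MP heterosis|, |HP heterosis| and parental genetic
distance — heterosis enters in absolute value; the additive effect is
already nonnegative. The analysis defaults to the Gaussian-kernel
GBLUP's predictions but is model-configurable.

# The synthetic-data generator

`simulate_study()` emulates the study system the package is designed
for: 132 inbred accessions genotyped at 3,000 genome-wide SNPs with MAF
drawn from U(0.05, 0.5), 20 of them crossed into 156 F1s, and traits
measured over 3 years at a target $h_b^2$ of 0.9. Choices that were
genuinely open, and why they were made:

* **Residual heterozygosity 0.10.** Inbreds are highly but not
  perfectly homozygous. With allele frequencies in U(0.05, 0.5), the
  expected F1 heterozygosity is ~0.3, so a residual inbred rate of 0.10
  reproduces the reported relation that F1s carry roughly 2.5-3x the
  heterozygosity of the inbred panel.
* **Effect-size law.** Additive effects are standard normal draws
  rescaled so the founder-panel additive variance is 1 — the simple
  infinitesimal-style assumption GBLUP itself encodes.
* **Dominance: directional, sparse, low-MAF.** Observed heterosis in
  this system is predominantly positive and is hypothesized to arise
  from complementation of dominant alleles at a few specific loci rather
  than genome-wide divergence (parental genetic distance does not
  correlate with heterosis). The generator therefore places positive
  dominance effects on a small subset (default 8) of the QTL, sampled
  with preference for low-MAF loci, and rescales them so the
  founder-panel ratio of dominance-deviation to additive variance equals
  `dominance_ratio`. This yields strong-heterosis proportions in the
  realistic 50-70% range at moderate dominance rather than saturating,
  and hybrids of phenotypically similar low-value parents show the
  largest high-parent heterosis. A `DWP`-like trait receives *negative*
  directional dominance and a negative genetic correlation with the
  content traits, mirroring the opposite heterosis pattern of
  placental dry weight.
* **Noise calibration.** Given the realized genetic variance
  $\sigma_g^2$ of the simulated panel,
  $\sigma_\varepsilon^2 = \sigma_g^2\, n\,(1-h^2)/h^2$, so the
  accession-mean heritability equals the target in expectation.
* **Crosses.** Distinct unordered parent pairs with reproducible
  mother/father orientation; true F1 genotypes by Mendelian gamete
  sampling. Reciprocal-cross effects are not simulated (the analysis
  ignores reciprocal differences by design). No linkage map, no
  recombination beyond the F1, no epistasis, no genotype-by-year
  interaction beyond additive year offsets.

What passing tests on this generator do **not** show about real data:
real capsaicinoid QTL are linked and epistatic, field noise is not
i.i.d. Gaussian across years, panel structure is not exchangeable, and
real MAF spectra are not uniform. The generator validates the
*machinery* — formulas, estimators, leakage discipline, and the
qualitative dominance mechanism — not field-scale accuracy claims.

# The dominance-error mechanism

`sweep_dominance()` reruns the single-trait workflow at dominance ratios
{0, 0.5, 1} with shared seeds, so the founder panel, crosses and effect
draws are identical across ratios and only the dominance magnitude
changes. Under the package's test conditions (132 inbreds, 1,500 loci,
156 F1s, 3 seeds) this reproduces the qualitative mechanism: the
strong-heterosis proportion rises (roughly 15-20% to 55-75%), the
Gaussian-kernel GBLUP accuracy falls (roughly 0.83 to 0.35-0.4), and at
full dominance the per-F1 RSE correlates strongly and significantly
positively with |MP heterosis|.

One caveat discovered while validating the null case: even with *zero*
dominance, RSE and |MP heterosis| are mechanically correlated, because
the BLUP noise in $P_{F1}$ enters both the heterosis numerator and the
prediction error. A "no significant correlation under a purely additive
trait" null check is therefore not a valid expectation at high
heritability, and the package does not assert it; the discriminating
signatures of real dominance are the monotone accuracy loss and the
rise of the strong-heterosis class.

# Numerical and design decisions

* **Training-data discipline.** Models are trained on inbred accessions
  only. The pipeline enforces this twice: a hard error if any F1 id
  appears in the training genotype panel, and training BLUPs refit from
  inbred phenotype records alone — so F1 phenotypes cannot influence
  model fitting even through variance-component estimates. Heterosis
  tables and observed F1 values use the joint all-accession fit, which
  is the natural basis for comparing F1s with their parents on one
  scale. The test suite verifies that mutating every F1 phenotype
  leaves all predictions bit-identical.
* **MAF filter.** Strictly greater than the threshold (default 0.05),
  applied to the training panel; idempotent; an all-loci-removed result
  is an error, not an empty matrix.
* **Missing genotype calls.** VCF sites with any missing call (or
  multi-allelic sites) are dropped panel-wide with a reported count —
  the simplest policy consistent with a small curated SNP panel. TSV
  input must be complete. No imputation, no LD pruning, no phasing.
* **Polarity.** Reference/alternate polarity is arbitrary but must be
  consistent across parents and F1s; flipping the coding at any subset
  of loci leaves distances, all three kernels and kernel predictions
  invariant (tested).
* **Variance estimates.** lme4 bounds variance components at zero;
  kernel REML clamps eigenvalues at zero and variance ratios to
  $e^{\pm 12}$. Degenerate fits (constant predictions) are reported
  explicitly with a reason code rather than silently as `NA`.
* **Determinism.** Every simulation and every stochastic trainer is a
  pure function of its inputs and a seed; reruns of the pipeline with
  the same configuration are identical.
* **Problem sizes in tests.** The validation suite uses panels of
  20-150 accessions and 50-3,000 loci, 5 replicate seeds for the
  cross-prediction recovery benchmark and 3 for the dominance sweep —
  sizes at which the parameter-recovery targets (REML components within
  15%, F1 accuracy $\ge$ 0.8 on an additive trait) are comfortably
  identifiable.

# Known limitations

* Percent heterosis is undefined for traits that can take non-positive
  accession values; such records are excluded, not rescued.
* The F1 count and SNP panel size of the motivating system are reported
  inconsistently in its source (156 vs 159 F1s; 3,149 vs 3,194 SNPs);
  the package treats both as free configuration and always reports `n`
  alongside every correlation.
* The two-kernel (additive + dominance) REML uses direct numerical
  maximization with restarts rather than an exact AI-REML; on panels of
  a few hundred accessions this is fast and reliable, but it is not
  intended for panels orders of magnitude larger.
* Gibbs samplers report posterior means and basic chain summaries, not
  full convergence diagnostics; for publication-grade Bayesian analyses
  run multiple chains at longer lengths.

# Worked example

```{r, eval = FALSE}
library(crossgp)

cfg <- sim_config(n_inbred = 132, n_loci = 1500, n_parents = 20,
                  n_f1 = 156, dominance_ratio = 0.5, seed = 1)
st  <- simulate_study(cfg)
ph  <- derive_traits(st$phenotypes)

res <- run_pipeline(st$genotypes, ph, st$crosses,
                    traits = c("CAPgDW", "TCAPgDW", "DWP"),
                    models = c("gblup_a", "gblup_gauss", "ridge", "rf"),
                    seed = 1)

res$h2                        # variance components and heritability
res$heterosis_summary$groups  # non / medium / strong proportions
res$accuracy                  # Pearson r per trait and model
res$error_factors             # RSE vs heterosis, additive effect, distance
```
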