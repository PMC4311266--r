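---
title: "Score-based rare-variant and haplotype meta-analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based rare-variant and haplotype meta-analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyrare)
```

## The problem

Exome-chip association studies of glycaemic traits (fasting glucose in
mmol/l, log fasting insulin, type 2 diabetes status) pool tens of thousands
of participants across cohorts that cannot share individual-level data. The
practical solution is a two-stage design: each cohort fits a null model and
exports per-gene *score statistics* — the score vector $U$ and its
covariance $V$ — and the meta-analysis stage combines these sufficient
statistics into single-variant, gene-based, conditional and haplotype
results. glyrare implements both stages plus a synthetic-cohort generator
that reproduces the statistical structure this machinery assumes, so every
stage is testable end-to-end without access to consortium data.

## Cohort stage: null models and score statistics

For a quantitative trait the null model is $Y = X\beta + b + \varepsilon$
with an optional family random intercept $b \sim N(0, \sigma_b^2)$ shared
within sibship and $\varepsilon \sim N(0, \sigma_e^2)$. Because the only
random effect is exchangeable within family blocks, the marginal covariance
is $\sigma_e^2 I + \sigma_b^2 J$ per block and REML profiles down to a
one-dimensional search over the variance ratio
$\lambda = \sigma_b^2/\sigma_e^2$. `fit_null()` performs this profiled REML
with a bracketed scalar optimizer (tolerance $10^{-8}$, $\lambda \in
[0, 1000]$, the $\lambda = 0$ boundary checked explicitly); unrelated
cohorts reduce exactly to ordinary least squares. Binary traits use
logistic regression after reducing each family to one member, as consortium
practice dictates when no kinship-aware logistic machinery is available.

`score_stats()` whitens the genotype columns by the fitted block
covariance, residualises them on the covariate design, and returns

$$U = \tilde G^\top \Sigma^{-1} r, \qquad V = \tilde G^\top \Sigma^{-1} \tilde G,$$

so that $U_j / V_{jj}$ is the per-allele effect estimate and
$U_j/\sqrt{V_{jj}}$ the score $z$-statistic. Binary traits use the logistic
score $U = G^\top(y - \hat\mu)$ with the expected information. Missing
dosages are imputed to the variant's mean dosage before residualisation
(the convention of score-based meta-analysis frameworks; with no missing
data the imputation path is exactly the complete-data path). Zero-variance
variants contribute $U_j = 0$, $V_{jj} = 0$ and are flagged rather than
dropped, so variant lists stay aligned across cohorts.

## Meta stage: summation, SKAT, burden, conditional

`combine_scores()` sums $U$ and $V$ element-wise over the union variant
list, harmonising allele orientation by flipping the sign of $U_j$ and the
$j$-th row/column of $V$ when a cohort coded the other allele. Variants
absent from a cohort contribute zeros; pooled MAF is the allele-count
weighted mean over contributing cohorts (the closest reproducible analogue
of a chip-wide MAF computed on a jointly called set).

The gene-based tests follow the standard forms:

* **SKAT**: $Q = \sum_j w_j^2 U_j^2$ with Beta(1, 25)-density weights on
  pooled MAF ("Wu weights"); the null distribution is
  $\sum_i \lambda_i \chi^2_1$ with $\lambda$ the eigenvalues of $W V W$.
* **Weighted-sum burden (WST)**: $S = \sum_j w_j U_j$ with Madsen–Browning
  weights $w_j = 1/\sqrt{n \hat p_j (1 - \hat p_j)}$, tested two-sided
  against $N(0, w^\top V w)$. We use pooled all-sample MAF in the weights
  for both trait kinds (the original proposal weighted by control-only
  frequencies; pooled frequencies are deterministic in a score-only
  pipeline and the difference is negligible at the rare frequencies the
  filters admit).

Quadratic-form tail probabilities are computed by characteristic-function
inversion (Imhof's integral) with `stats::integrate` at relative tolerance
$10^{-9}$. Adaptive quadrature cannot resolve the wildly oscillatory
integrand far into the tail, and can fail *silently* there, so the result
is accepted only when it agrees with the Liu four-moment approximation to
within 0.1; otherwise the Kuonen saddlepoint approximation is used (exact
chi-square when all eigenvalues coincide, which also covers one-variant
genes), with Liu as the final fallback. Each result records which method
produced its p-value.

Conditional analysis is the covariance projection
$U^* = U - V_{gc} V_{cc}^{-1} U_c$, $V^* = V - V_{gc} V_{cc}^{-1} V_{cg}$;
a near-singular $V_{cc}$ (reciprocal condition number below $10^{-12}$) is
ridged by $10^{-8} \times \mathrm{tr}(V_{cc})$ on the diagonal and the
regularisation is recorded. Conditioning variants remain in the output with
exactly zero score. The projected score components equal the
residualisation on the augmented design exactly; the projected $z$ retains
the null model's residual variance, so it differs from a re-fitted
regression's Wald $z$ by the factor $\hat\sigma_{\text{null}}
/ \hat\sigma_{\text{aug}}$ — the standard behaviour of score-based
conditional analysis.

Filters default to the published scheme: single-variant tests require
pooled MAC $\ge 20$; gene-based tests keep protein-altering variants
(nonsynonymous, splice-site, stop gain/loss) with MAF $< 1\%$ and require
cumulative MAC $\ge 20$ (quantitative) or $\ge 40$ (binary); thresholds are
Bonferroni at $\alpha = 0.05$ over the declared test count. The binary-trait
single-variant filter is implemented as MAC $\ge 20$ among cases, with MAF
restated from the full sample, since the published phrasing leaves the MAF
denominator ambiguous. Direction-consistency against previously reported
effects uses the exact binomial tail
$\sum_{i=k}^n \binom{n}{i} 2^{-n}$, computed in log space.

## The haplotype model and its meta-analysis

The distinctive component is a haplotype association model that works from
summary statistics across cohorts with *different* haplotype sets.

**EM dosages.** `em_dosages()` estimates haplotype frequencies under
random mating by EM over the compatible diplotypes of each unphased
genotype, grouping individuals by genotype pattern so the cost scales with
pattern count, not sample size. Missing genotypes are marginalised over
compatible pairs. Initialisation is the deterministic product of observed
allele frequencies, so the default path has no seed sensitivity. The
expected dosage $h_m = E[\text{copies of haplotype } m \mid \text{genotypes}]$
is an integer whenever phase is unambiguous (at most one heterozygous
site). Haplotypes with converged frequency below $10^{-6}$ are pruned and
dosage rows renormalised to sum to exactly 2. The EM log-likelihood is
non-decreasing by construction and is asserted per iteration in the tests.

**Cohort fit.** `fit_hap_model()` fits
$Y = X\beta + \sum_{m \ne \text{ref}} h_m \gamma_m + b + \varepsilon$ with
the most frequent haplotype as reference (effect fixed at 0), by the same
profiled-REML machinery as the null model. REML with plug-in variance
components is used for the $\gamma$ covariance — whether the original
analysis used ML or propagated variance-estimation uncertainty is not
recorded anywhere we could find, and plug-in REML is the conservative
standard. Collinear dosage columns are resolved by dropping the rarest
offending haplotype, with a logged warning.

**Meta-analysis.** `meta_hap()` realises multi-parameter fixed-effects
meta-analysis as GLS stacking with selection maps: with $S_c$ mapping the
union haplotype set to cohort $c$'s set,

$$\hat\gamma_{\text{meta}} = \Big(\sum_c S_c^\top \Sigma_c^{-1} S_c\Big)^{-1}
  \sum_c S_c^\top \Sigma_c^{-1} \hat\gamma_c,$$

with the inverted pooled information as covariance. This is what lets each
cohort contribute uniquely observed haplotypes. The global test is the Wald
statistic against $\chi^2$ with $df = |\text{union}| - 1$: only summary
statistics cross the cohort boundary, so a likelihood-ratio global test is
not available in the meta-analytic setting, and Wald is the natural choice.
A per-coordinate scalar inverse-variance mode (`mode = "scalar"`) is
provided for sensitivity checks; it coincides with the multivariate mode
exactly when all cohort covariances are diagonal. All cohorts must share
the reference haplotype; re-parameterising a fit against a different
reference is out of scope and raises an error — the generator (and any
sensible consortium plan) guarantees a shared, common reference.

Haplotype labels are the allele strings themselves, which makes
cross-cohort identity automatic provided cohorts use a harmonised variant
list; the pipeline therefore defines the haplotype variant set as the
annotated protein-altering variants, not the per-cohort frequency-filtered
set.

## What the synthetic generator emulates — and what it does not

`build_g6pc2_like_pool()` encodes the architecture that motivated the
haplotype method: 16 variants, one common regulatory-like variant (implied
MAF drawn in [0.38, 0.42]), 15 rare protein-altering variants (cumulative
implied MAF 1.6%, each below 1%), each rare minor allele carried on exactly
one haplotype. Haplotypes are drawn multinomially and independently for the
two gametes (Hardy–Weinberg), which is exactly the assumption of the EM it
exercises. Families are sibships sharing one random intercept — matching
the fitted model rather than a full kinship structure. Binary traits apply
a logistic link to the same linear predictor with the intercept solved
numerically for a configurable prevalence (default 0.15, a realistic
case fraction for a mixed population-and-case-enriched consortium).

The generator deliberately omits: linkage disequilibrium beyond haplotype
sharing, genotyping error, chip-versus-sequencing platform differences,
population stratification, and trait non-normality. Passing tests therefore
demonstrate the *statistical machinery* is correct under its stated
assumptions; they do not validate robustness to the artefacts real cohort
data add on top.

Default generator values used by the packaged demo: three family cohorts
(sibship sizes 1/2/3 with probabilities 0.6/0.25/0.15), family SD 0.3 and
residual SD 0.8 trait units, opposing-direction effects (+0.5, −0.45,
+0.45) on three rare-allele haplotypes — the regime in which a variance
component test and the global haplotype test detect association while a
signed burden test cancels to null, which is the scientific point the demo
illustrates.

## Numerical choices and degenerate inputs

* Allele-frequency ties at exactly 0.5 are never flipped during
  minor-allele recoding, making recoding deterministic and idempotent.
* Coordinates are 1-based VCF positions; the conditional candidate window
  is the half-open interval $[\text{pos} - 500\,\text{kb},
  \text{pos} + 500\,\text{kb})$.
* Interchange JSON is written at full precision (`digits = NA`), so
  write/read round trips preserve all numerical fields to $10^{-12}$ or
  better.
* Singular designs, absent conditioning variants, mismatched references,
  dropped reference haplotypes, zero-sign inputs to the direction test and
  degenerate (monomorphic) haplotype inputs all raise classed conditions
  rather than producing silent numbers.
* All randomness flows from one integer seed through `mix_seed()`, which
  folds a stream index into the master seed while staying inside 32-bit
  integer range; cohort draws mix the cohort index into the stream.

## Problem sizes used by the test-suite simulations

Calibration suites use 2,000 null replicates (cohorts of $n = 1000$ with
five rare variants for SKAT/WST; five cohorts of 300 with six haplotypes
for the global haplotype test); recovery suites use 100–200 replicates at
$n = 1000$–$30{,}000$; the permutation oracle uses 20,000 permutations at
$n = 200$. These sizes give Monte-Carlo standard errors comfortably inside
the asserted bounds (e.g. $\pm 0.005$ on a 0.05 rejection rate) while the
whole suite stays quick enough to run routinely.

## Known limitations

* No kinship-matrix mixed models: relatedness is sibship-block only, and
  binary traits drop relatives instead of modelling them.
* No binary-trait haplotype model; the haplotype machinery is
  quantitative-trait only.
* No heterogeneity statistics, random-effects meta-analysis, or genomic
  control; the combination rules are fixed-effects throughout.
* The EM enumerates diplotypes, which is tractable to roughly 25 variants
  and breaks down for highly ambiguous patterns (a classed error is raised
  rather than returning an approximation).
* X/Y/mitochondrial variants, multiallelic records and external phasing
  reference panels are out of scope.

## A worked example

```{r demo, eval = FALSE}
cfg <- run_config(system.file("extdata", "demo_config.yaml", package = "glyrare"))
cfg$out_dir <- tempfile("glyrare-demo-")
res <- run_pipeline(cfg)

res$gene          # SKAT strongly significant, burden null (opposing effects)
res$hap$global_p  # global haplotype test agrees with SKAT
format_hap_table(res$hap)
```

The README shows the printed output of this run and walks through its
interpretation.
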