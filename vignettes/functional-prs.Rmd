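---
title: "Functional polygenic risk scores from SMR/HEIDI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional polygenic risk scores from SMR/HEIDI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most disease-associated variants found by genome-wide association studies
(GWAS) sit in non-coding regions, and only some of them act through a
measurable molecular mechanism such as gene expression or DNA methylation.
A natural question for risk prediction is whether restricting a polygenic
risk score (PRS) to *putatively functional* variants — those whose disease
association is statistically consistent with mediation through a molecular
trait — preserves or improves discrimination relative to an agnostic
GWAS-derived PRS. `smrprs` implements the full analysis chain needed to ask
that question: nomination of functional variants by summary-data Mendelian
randomization (SMR) with a heterogeneity filter (HEIDI), PRS construction
and scoring with plink-`scoresum` semantics, and a battery of
discrimination analyses. Because the individual-level cohorts this design
needs are access-restricted in practice, the package ships a synthetic-data
module that emulates every input at desk scale with known ground truth, so
each stage is testable end to end.

## SMR: one instrument, two samples

For a variant $z$, a molecular trait $x$ (an expression probe or CpG
methylation level) and a disease $y$, two independent studies provide
marginal effect estimates: $\hat b_{zx}$ (QTL study) and $\hat b_{zy}$
(GWAS, log-odds scale). The two-step least-squares (ratio) estimate of the
effect of the molecular trait on disease is

$$\hat b_{xy} = \hat b_{zy} / \hat b_{zx},$$

and the SMR test statistic combines the two z-scores
$z_{zy} = \hat b_{zy}/\mathrm{se}(\hat b_{zy})$,
$z_{zx} = \hat b_{zx}/\mathrm{se}(\hat b_{zx})$ as

$$T_{\mathrm{SMR}} \;=\; \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2}
\;\sim\; \chi^2_1 \text{ under } H_0: b_{xy}=0 ,$$

with $\mathrm{se}(\hat b_{\mathrm{smr}}) = |\hat
b_{\mathrm{smr}}|/\sqrt{T_{\mathrm{SMR}}}$. Two useful consequences are
baked into the test suite: $T_{\mathrm{SMR}} \le \min(z_{zy}^2, z_{zx}^2)$
for every record, and the p-value is invariant to jointly flipping the
effect alleles of both studies.

```{r}
library(smrprs)
compute_smr(b_zy = 0.3, se_zy = 0.05, b_zx = 0.8, se_zx = 0.1)[c("b_smr", "t_smr", "p_smr")]
```

## HEIDI: distinguishing pleiotropy from linkage

A significant $T_{\mathrm{SMR}}$ is compatible with two very different
genetic architectures: *pleiotropy* (one causal variant drives both the
molecular trait and the disease) and *linkage* (two distinct, correlated
variants each drive one trait). Under pleiotropy every cis-SNP in LD with
the causal variant estimates the *same* $b_{xy}$; under linkage the ratio
estimates disagree. HEIDI tests this homogeneity: for each instrument $i$
besides the top QTL SNP,

$$d_i = \hat b_{xy}(i) - \hat b_{xy}(\mathrm{top}), \qquad
T_{\mathrm{HEIDI}} = \sum_i z_{d_i}^2,$$

where $z_{d_i}$ standardizes $d_i$ by its delta-method standard error. The
GWAS and QTL samples are independent, and within each study the cross-SNP
covariance of effect estimates is proportional to the signed LD correlation
$r_{ij}$, so the covariance of the ratio estimates is

$$\mathrm{cov}(\hat b_{xy,i}, \hat b_{xy,j}) \approx
\frac{r_{ij}\,s_{zy,i}\,s_{zy,j}}{b_{zx,i}\,b_{zx,j}} +
\frac{r_{ij}\,s_{zx,i}\,s_{zx,j}\,b_{zy,i}\,b_{zy,j}}{b_{zx,i}^2\,b_{zx,j}^2}.$$

Because the $z_{d_i}$ are correlated, $T_{\mathrm{HEIDI}}$ is referred to a
*weighted sum of 1-df chi-squares* whose weights are the eigenvalues of the
correlation matrix of the $z_d$ vector. A probe is declared pleiotropic —
and its top SNP nominated as functional — when $p_{\mathrm{SMR}} < 5\times
10^{-8}$ **and** $p_{\mathrm{HEIDI}} > 0.05$. Both thresholds are exposed
in `run_smr_scan()` but default to these fixed values; no FDR layer is
added.

### Instrument selection

The literature leaves instrument selection to the implementation, so
`heidi_config()` exposes it fully, defaulting to the conventions of the
reference SMR software: candidate instruments need QTL $p < 1.57\times
10^{-3}$ ($|z| > 3.16$, so the ratio's denominator is well away from zero),
LD with the top SNP within $r^2 \in [0.05, 0.9]$ (below, the instrument
carries no information about a shared causal variant; above, the covariance
matrix becomes numerically singular), at most 20 instruments (smallest QTL
p first), and at least 3 before a p-value is reported at all.

### The weighted chi-square tail

`weighted_chisq_tail()` computes $P(\sum_i w_i \chi^2_{1,i} > q)$ by
numerically integrating Imhof's inversion formula. The integrand oscillates
at a frequency bounded by $(\sum w_i + q)/2$ under an algebraically
decaying envelope, so the implementation uses composite Simpson quadrature
with a fixed number of nodes per oscillation up to an explicit truncation
point chosen from the envelope; this is accurate to better than $10^{-6}$
against exact chi-square cases across the weight ranges HEIDI produces,
where generic adaptive quadrature (which assumes eventually-monotone tails)
can stall. The Liu–Tang–Zhang moment-matching approximation is available as
`method = "ltz"`; it is exact for equal weights and faster, but only
approximate (about $10^{-3}$) for strongly unequal weights, which is why
integration is the default. Tests validate the tail against Monte-Carlo
draws and closed-form chi-square identities, never against the
implementation itself. `q = 0` returns exactly 1, and results are clamped
to $(10^{-300}, 1]$.

## PRS construction and scoring

A PRS model is a table of variants with effect alleles and per-allele
weights $\beta_k$; an individual's score is $\sum_k \beta_k x_k$ with $x_k$
the effect-allele dosage in $[0,2]$ (`scoresum` semantics). The functional
model collects the unique passing top SNPs over any number of scans (eQTL
and mQTL), weighted by their GWAS log-odds effects; `combine_models()`
takes a set union and *refuses* to merge models that disagree on a shared
variant's weight, since a combined score is only meaningful under a single
weight source. Scoring details follow plink:

* missing dosages are imputed at $2\times$ the effect-allele frequency of
  the scoring cohort, keeping score totals comparable across individuals;
* model variants absent from the cohort are skipped and counted, never
  fatal — real cohorts differ in imputation coverage;
* allele codings are reconciled per variant ($x \to 2-x$ when the model's
  effect allele is the cohort's other allele), which shifts each
  individual's score by a constant and therefore cannot change any
  rank-based metric.

LD pruning (`ld_prune()`) interprets the conventional "LD < 0.9" as $r^2 <
0.9$ and scans variants greedily in genomic order, dropping a variant when
its $r^2$ with any retained earlier variant exceeds the threshold. Keeping
the earlier variant (rather than the larger-weight one) makes the result
deterministic and order-stable; the threshold is a parameter throughout.

## Evaluation

`eval_report()` bundles the discrimination analyses:

* **AUC** is the Mann–Whitney probability that a random case outscores a
  random control (ties one half), with a DeLong 95% CI (via pROC); tests
  verify it against exhaustive pair enumeration.
* **OR per SD** comes from univariable logistic regression on the score
  standardized by the pooled-sample SD. The pooled SD is the default
  because the source analyses say only "per standard deviation change";
  a control-only SD is available via `sd_scope`.
* **Youden operating point** sweeps midpoints between adjacent distinct
  scores for the rule `score > threshold`; ties in $J$ resolve to the
  smallest qualifying threshold, which maximizes sensitivity at equal $J$.
* **Centile rule**: the high-risk threshold is the 80th centile (type-7
  quantile, the ubiquitous default; configurable) of the *control* score
  distribution, and "high risk" means strictly exceeding it. With distinct
  control scores and a control count divisible by 5 this pins specificity
  at exactly 0.8. For any single-threshold classifier the ROC curve is two
  segments, so its AUC is $(\mathrm{sens}+\mathrm{spec})/2$ — an identity
  asserted in every report. Note that scores built from a handful of
  variants take few distinct values; ties at the threshold then push
  specificity slightly above the nominal level, which is behaviour, not
  error.
* **Overlap analysis** applies the centile rule to two scores and
  cross-tabulates the flags within cases and controls — near-identical
  AUCs can hide substantially different high-risk sets, which is exactly
  what `compare_weightings()` quantifies for two weightings of one variant
  panel.

Prospective cohorts are evaluated identically to case–control data
(incident case = 1); no time-to-event modelling is attempted.

`subsample_auc()` addresses variant-count imbalance between two scores: it
repeatedly draws $i$ variants uniformly without replacement (1000
iterations in the reference design), rescores, and summarizes the AUC
distribution by median, IQR and range. A master seed spawns per-iteration
substreams, so the experiment is reproducible and its iterations
order-independent.

## The synthetic-data module

Every generator is a pure function of its inputs and a seed.

* **Reference panel** (`make_reference_panel()`): variants live in
  independent LD blocks, one block per chromosome. Within a block, each
  haplotype's allele indicators share an equicorrelated Gaussian copula
  thresholded at the MAF quantile; two independent haplotypes per
  individual give Hardy–Weinberg genotypes whose dosage correlation equals
  the haplotype correlation. The latent correlation is *calibrated* (via
  the bivariate normal CDF) so the realized allele correlation matches the
  requested $r$. One modelling consequence worth knowing: the correlation
  of two Bernoulli variables with unequal frequencies is bounded below 1,
  so tightly linked variants must have nearly equal MAFs — the generator
  therefore shrinks within-block MAF dispersion proportionally to $(1-r)$,
  which is also what real LD blocks look like.
* **Architectures** (`architecture_spec()`): `pleiotropy` gives the causal
  variant a molecular effect $b_{zx}$ and the disease a mediated log-odds
  effect $b_{zx} b_{xy}$ (the mediation identity); `linkage` attaches the
  disease effect to a *different* variant in LD with the QTL variant;
  `null` zeroes everything.
* **QTL studies** (`make_qtl_study()`): an independent sample is drawn from
  the panel's population, the molecular trait is simulated, and per-variant
  simple linear regressions produce the marginal summary statistics that
  QTL consortia distribute. An optional p-value cap mimics "lite" releases
  that ship only significant records.
* **GWAS** (`make_gwas_study()`): disease status follows a logistic model
  linear in dosage (no liability threshold), sampled to the requested case
  and control counts; marginal per-variant logistic regressions (a
  vectorized Newton solver) yield COJO-style records. The logistic choice
  matches the marginal-logistic form the GWAS side of SMR assumes and is
  closed under case-control sampling (only the intercept shifts).
  Monomorphic variants keep their row with a non-finite SE and a $p = 1$
  sentinel.
* **Cohorts** (`make_cohort()`): outcomes are drawn from a logistic model
  whose linear predictor is the true PRS; missingness is completely at
  random, matching what frequency imputation assumes.

What the generator deliberately does **not** emulate: realistic
genome-wide LD (blocks are independent and equicorrelated), population
stratification and relatedness, imputation uncertainty (dosages are hard
0/1/2), genotyping batch effects, and covariates such as age. Passing tests
therefore demonstrate the *statistical machinery* — calibration of the
tests, correctness of the scoring arithmetic, propagation of signal — not
performance claims about any real cohort.

## Study conditions used in tests and the demo pipeline

The default pipeline emulates the motivating breast-cancer analysis at desk
scale: 12 LD blocks of 25 variants (r = 0.55, MAF 0.1–0.5), a panel of
1,000 individuals, eQTL and mQTL studies of 2,000 and 1,200, a GWAS of
8,000 cases and 8,000 controls, and a scoring cohort of 1,780 cases and
1,690 controls (the real design's 3,560/3,383 at half scale; the control
count stays divisible by 5 so the centile rule is exact). Six eQTL and six
mQTL probes mix strong pleiotropy ($b_{zx}=0.6$, $b_{xy}=0.4$, chosen so
the causal variant reaches $z_{zx}\approx 15$ and $z_{zy}\approx 8$ —
comfortably clearing both filters, as the reference analysis's hits did),
linkage ($b_{zy}^{\mathrm{direct}}=0.25$ two variants away), and null
probes. Calibration experiments (HEIDI type-I error, ratio-estimate
recovery) run 500 replicates on a single 25-variant block with a QTL study
of 1,500 and a GWAS of 5,000 — sizes at which the asymptotics the tests
rely on are comfortably in force while a full replicate set completes in
minutes.

## Numerical and degenerate-input policy

* `compute_smr` flags records with $b_{zx}=0$ or non-finite SEs as
  non-computable rather than returning infinities; $b_{zy}=0$ returns the
  exact null ($T=0$, $p=1$).
* `compute_heidi` reports an absent p-value below the instrument floor and
  errors (naming the probe) on invalid covariance structures; eigenvalues
  below $10^{-8}$ are dropped as numerically null directions.
* `youden_point` warns and returns $J=0$ when all scores are identical.
* Allele harmonization is strand-agnostic; palindromic variants are
  resolved by allele frequency only when both frequencies are informative
  ($|\mathrm{eaf}-0.5|>0.08$), otherwise dropped and counted.
* Every pipeline artifact is free of timestamps and machine-specific
  paths, so a rerun under the same configuration is bit-identical and the
  provenance record (md5 per file) can prove it.

## Known limitations

Single-SNP SMR only (no multi-SNP or colocalization alternatives); no
trans-QTL analysis; no penalized re-estimation of weights (external weight
files are loaded, not trained); no survival modelling for prospective
designs; LD is always estimated from the supplied panel, so panel/cohort
population mismatch — a real concern in applications — is out of scope for
the synthetic study design.
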