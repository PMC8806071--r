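---
title: "Models and methods in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

`mrpipe` implements the causal-inference workflow of a two-sample
Mendelian randomisation (MR) study of continuous exposures (obesity
indices such as BMI, WHR, WHRadjBMI, in SD units) and binary disease
outcomes (reproductive conditions, as log odds ratios), together with
multivariable and mediation MR, stratified non-linear MR, mixture-model
clustering of per-variant estimates, and a parallel observational arm.
This vignette describes the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology left a
genuine choice.

## The instrumental-variable model

For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association
with the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its
association with the outcome, taken from non-overlapping GWAS samples.
Under the instrumental-variable assumptions (relevance, independence
from confounders, and exclusion from direct outcome pathways), each SNP
yields a Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ (`wald_ratio()`; the
second-order SE that propagates $\sigma_{Xj}$ is available behind a
flag).

* **IVW** (`mr_ivw()`): weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ through the origin with weights $1/\sigma_{Yj}^2$.
  The default is the fixed-effect estimator — the residual scale is
  pinned at 1 so the SE is $1/\sqrt{\sum_j \hat\beta_{Xj}^2/\sigma_{Yj}^2}$
  — matching the fixed-effect meta-analytic framing of the rest of the
  pipeline; a multiplicative random-effects toggle inflates the SE by
  $\max(1, \sqrt{Q/\mathrm{df}})$. Cochran's $Q$ is the weighted
  residual sum of squares on $n-1$ df. A single SNP reduces exactly to
  the Wald ratio.
* **MR-Egger** (`mr_egger()`): the same weighted regression with a free
  intercept, after orienting all $\hat\beta_{Xj} \ge 0$. The intercept
  estimates average directional pleiotropy; $Q'$ is the analogous
  heterogeneity statistic on $n-2$ df. Egger's slope is consistent
  under the InSIDE assumption even when every instrument is invalid,
  at a substantial cost in precision.
* **Weighted median** (`mr_weighted_median()`): the weighted median of
  the per-SNP Wald ratios with inverse-variance weights, interpolated
  at standardised cumulative weight 0.5. It is consistent while less
  than half of the instrument *weight* is invalid. The SE comes from a
  parametric bootstrap (default 5,000 resamples; the seed is a
  mandatory argument because the bootstrap is the only stochastic step
  in the estimator stack).
* **Model selection** (`rucker_select()`): IVW is reported unless its
  $Q$ is significant at `alpha_q` (default 0.05) *and* the heterogeneity
  absorbed by the Egger intercept ($Q - Q'$, $\chi^2_1$) *and* the
  intercept itself are both significant — the heterogeneity-guided
  trade-off between power and pleiotropy robustness. The published
  analysis this pipeline emulates reports $Q'/Q > 0.876$ with
  non-significant intercepts everywhere, a regime in which the tree
  always returns IVW; the threshold `alpha_q` is our default since the
  original analysis does not state one.

Diagnostics: `instrument_f()` computes the instrument $F$-statistic as
the mean of $(\hat\beta_{Xj}/\sigma_{Xj})^2$; `mr_steiger()` compares
instrument $r^2$ in exposure versus outcome via Fisher-transformed
correlations; `power_binary()` gives the analytic power of a
binary-outcome MR test from the outcome GWAS size, case fraction,
instrument $r^2$ and true OR; `het_between()` is the two-sample z-test
used to compare estimates between analyses (e.g., waist against hip
circumference).

## Harmonisation

`harmonize()` aligns outcome effects to the exposure's effect allele:
matching alleles are kept, swapped alleles negate the outcome beta and
complement the frequency, and strand flips are resolved by
complementing before comparison. Palindromic (A/T, C/G) variants carry
no strand information in their allele codes, so by default
(`infer-by-eaf`) they are aligned by which side of 0.5 the effect-allele
frequency falls on, and dropped as ambiguous when
$\min(\mathrm{eaf}, 1-\mathrm{eaf})$ is within `eaf_window` (default
0.08) of 0.5 or when a frequency is missing; the `drop` policy removes
all of them. These defaults are common two-sample MR practice; they are
exposed as configuration because the emulated study does not state its
choices. p-values are always recomputed from beta/SE by a two-sided
normal test, treating the input p column as advisory.

`meta_analyze_fixed_ivw()` pools per-variant effects across studies
with inverse-variance weights (the FinnGen + biobank meta-analysis
design); single-source variants are carried through flagged.
`select_instruments()` applies the genome-wide threshold (default
$5\times10^{-9}$, the stricter level for densely imputed GWAS);
LD clumping is assumed done upstream, and instruments are treated as
independent throughout.

## Multivariable and mediation MR

`mvmr_ivw()` regresses outcome effects on the matrix of exposure
effects (no intercept, weights $1/\sigma_{Yj}^2$), giving each
exposure's effect conditional on the others, with conditional
$F$-statistics computed on residualised instrument effects. A
degenerate exposure whose instrument effects are all zero is dropped
with a warning rather than treated as collinearity, so the remaining
estimates equal their univariable counterparts.

Two-step mediation MR (`two_step_mediation()`) combines the total
effect $c$ (univariable MR), the exposure-to-mediator effect $a$
(univariable MR), and the mediator-to-outcome effect $b$ conditional on
the exposure (multivariable MR) into the indirect effect $ab$ and the
proportion mediated $ab/c$. The SE of the proportion uses the
first-order delta method treating $a$, $b$, $c$ as independent (they
come from non-overlapping GWAS sources):

$$\mathrm{SE} = \sqrt{\left(\frac{b\,s_a}{c}\right)^2 +
\left(\frac{a\,s_b}{c}\right)^2 +
\left(\frac{ab\,s_c}{c^2}\right)^2}.$$

This exact three-term formula reproduces, to the printed decimal, the
published 18.2%–82.2% interval for the leptin-mediated share of the
BMI–pre-eclampsia effect, which is why it is adopted as the implied
formula. Confidence bounds are truncated to [0, 1] only at the
reporting layer (published tables print "0%" lower bounds); the raw
bounds are preserved in the result object. `mediation_grid()` applies
the published gating: mediation is computed only where the total effect
passes FDR < 0.05 across the grid and both paths pass unadjusted
p < 0.05, with skipped triples recorded.

Proportion estimates are ratios of noisy quantities: their sampling
distribution is heavy-tailed when $c/s_c$ is small, and the delta
interval is a local approximation. The recovery benchmark therefore
works in a regime where the total effect is well determined.

## Non-linear MR

`iv_free_strata()` residualises the exposure on the genetic score (and
covariates) and stratifies on the residual ("IV-free exposure").
Stratifying on the raw exposure would condition on a collider between
the score and confounders and bias within-stratum estimates — the test
suite demonstrates this with a paired simulation in which raw-exposure
stratification produces a pooled estimate many times further from the
truth than IV-free stratification on the same cohort.

`lace_per_stratum()` computes the localized average causal effect
(LACE) in stratum $k$ as the ratio of the within-stratum logistic
coefficient of the outcome on the score to the full-sample linear
coefficient of the exposure on the score, with first-order SE. Using
the full-sample denominator keeps strata comparable; strata without
both cases and controls are excluded with a warning (the emulated
study restricted non-linear MR to outcomes above 5% prevalence for
exactly this reason). Defaults are 10 strata for the piecewise-linear
curve and 100 for the fractional-polynomial curve, both configurable.

`piecewise_fit()` integrates the LACE across strata into a continuous
piecewise-linear log-OR curve anchored at zero at the reference
exposure (midpoint of the lowest stratum — the reference is ours, as
the original does not state one), accumulating pointwise variances.
`fp_fit_and_test()` models the LACE as the *derivative* of a fractional
polynomial over the conventional power grid
$\{-2,-1,-0.5,0,0.5,1,2,3\}$ (power $p$ contributes the basis
$x^{p-1}$; $p=1$ is the constant-LACE, i.e. linear, reference), fitted
by weighted least squares. The non-linearity p-value compares the best
degree-1 model against the constant reference on 1 df — the convention
of the stratified-MR fractional-polynomial literature; degree 2 is
adopted only if it improves on degree 1 by $\chi^2_2$ at 0.05.
Repeated powers are not used in the derivative-space grid. The
acceptance suite measures the test's type-I error at a
moderately-powered configuration (10 strata, LACE signal-to-noise 2)
and finds it within [0.03, 0.07] at nominal 0.05.
`iv_heterogeneity_tests()` supplies the across-strata Cochran's Q and
the meta-regression trend test.

## Mixture-model clustering of per-SNP estimates

`fit_mixture()` clusters Wald ratios $\hat\theta_j$ (SE $s_j$) into a
null component $N(0, s_j^2)$, $k$ "substantial" components
$N(\mu_k, s_j^2)$ with shared means, and a broad zero-mean "junk"
component for estimates that group with nothing, fitted by multi-start
EM with known per-SNP variances. Design choices, made where the
originating algorithm's description leaves them open, and asserted
through simulation recovery rather than published cluster counts:

* the junk variance is `junk_scale` (default 10) times the largest
  $s_j^2$, floored at the empirical variance of $\hat\theta$ — without
  the floor a narrow junk density cannot absorb extreme outliers, and a
  singleton "substantial" component would claim them;
* a candidate model containing a substantial component with fewer than
  two maximum-a-posteriori members is disqualified: a variant that
  groups with no other is junk by definition;
* $k$ is chosen by AIC over $0..$`max_k`. BIC was evaluated and
  rejected: with a broad junk component in the model its heavier
  penalty absorbed genuinely 5-SE-separated clusters into junk in
  about a fifth of replicates, while AIC plus the singleton rule and
  post-selection merging recovers the correct two opposite-sign
  clusters in over 95% of replicates and finds no spurious clusters in
  null-only data. Both criteria are reported in the fit object;
* after selection, substantial components whose means are not separated
  by more than 3 z-units of their estimation error are merged (and a
  component indistinguishable from zero is absorbed into the null),
  followed by a final EM pass — this removes the overfitting mode in
  which one true cluster is split in two;
* convergence is declared at a relative log-likelihood change below
  `tol` (default 1e-8) within `max_iter` (default 1,000) iterations;
  the multi-start selection prefers converged starts.

`substantial_members()` applies the published "$\ge$ 80% assignment
probability" rule and reports each cluster's effect direction.

## Observational arm

`adjust_and_int()` regresses the exposure on covariates (age, age
squared, assessment centre, smoking in the emulated study; smoking is a
toggle because adjusting for it can itself induce collider bias) and
maps residual ranks through $\Phi^{-1}$ with the Blom offset 0.375
(ties share average ranks; the offset choice is ours, the original does
not state it). `logistic_or()` fits the per-SD odds ratio, refusing
separated or non-converged fits. `mfp_closed_test()` implements the
fractional-polynomial closed test for a logistic outcome: best FP2
against the covariate-only null on 4 df (overall association), against
linear on 3 df (non-linearity), and against best FP1 on 2 df — the
conventional dfs that charge each estimated power as one parameter.
Here FP2 includes repeated powers ($x^p$, $x^p\log x$), and the
exposure is shifted positive when needed. `aic_model_comparison()`
additionally fits a spline GAM via `mgcv::gam` and compares all models
by AIC; the GAM is deliberately an off-the-shelf call, not a bespoke
smoother.

## Synthetic data: what it emulates, and what it does not

`simulate_cohort()` generates unlinked biallelic genotypes
(frequencies uniform in `maf_range`), an exposure in SD units with
configurable instrument heritability, an optional mediator with its own
instruments, and a Bernoulli outcome from a logistic model with direct,
mediated, pleiotropic and optional non-linear terms; the intercept is
solved numerically for the target prevalence. Defaults mirror the
emulated study's conditions: 200 instrument SNPs (the published
instruments span roughly 190–270 SNPs), exposure variance explained
4.15% (the published BMI instrument), outcome prevalence 5%. Exposure
SNP effects are oriented positive, the trait-increasing-allele
convention of GWAS instrument lists. `cohort_to_sumstats()` computes
per-SNP associations — closed-form linear regression for continuous
traits, logistic *score* regression for the binary outcome (exact
per-SNP ML behind a flag; at desk scale the two agree well within one
SE) — on disjoint halves in two-sample mode.

The generator does **not** emulate linkage disequilibrium, ancestry
structure, relatedness, genotyping error, or sample overlap between
exposure and outcome GWAS. Passing benchmarks therefore demonstrates
the estimators' statistical properties under the stated generative
assumptions, not robustness to those data pathologies.

`benchmark_suite()` freezes five scenarios (null; linear effect
$\theta = 0.25$ at the study's instrument strength and scale;
30% invalid instruments with directional pleiotropy; a mediation chain
with half the effect mediated; a U-shaped curve). Two scenario-design
notes: the invalid-instrument scenario uses a strong instrument
(50 SNPs, $h^2 = 0.2$) with per-allele pleiotropy an order of magnitude
above the outcome-GWAS SE, because the weighted median's robustness
advantage is an asymptotic property that only identifies when invalid
ratio estimates separate from the valid cluster — an analytic bias
calculation, not benchmark iteration, fixed these values. The mediation
scenario uses $n = 50{,}000$ with mediator-instrument $h^2 = 0.2$ so
that regression-dilution from instrument-effect estimation error stays
below the recovery tolerance. Calibration-style checks (type-I error
over thousands of replicates) are run at the summary-statistic or
stratum-estimate level — the exact sampling model of the estimators —
because cohort-level generation at that replicate count would add
nothing but runtime; cohort-level generation is exercised by the
recovery and bias-ordering benchmarks. Problem sizes throughout the
test suite (cohorts of $10^4$–$2\times10^5$, 15–200 SNPs, 200
replicates for recovery means, 2,000–2,500 for calibration) were chosen
as the smallest at which the asserted properties are statistically
clearly resolved.

## Orchestration

`run_grid()` reproduces the analysis grid: harmonise each exposure ×
outcome cell, run all three estimators, select the reporting method by
the Rucker tree, and adjust the selected p-values by Benjamini–Hochberg
FDR across the grid (BH, not BY: the tests are close to independent;
the emulated study corrected 24 tests per analysis family, and we
likewise correct within each family). Reverse MR is the same grid with
roles swapped. Reports are written as TSV plus a JSON manifest
(`write_grid()`). The package's interface is its R functions; the
acceptance script under `scripts/` is the only command-line entry
point.

## Known limitations

* Weak-instrument bias: fixed-effect IVW with noisy instrument effects
  is attenuated by roughly $F/(F+1)$; at the emulated study's
  instrument strength ($F \approx 10$ on desk-scale samples, > 60 in
  the published data) this is visible but within the benchmarks'
  tolerances. No Winner's-curse or weak-instrument correction is
  implemented.
* The weighted median retains a finite-sample bias of order half the
  per-ratio SE under one-sided contamination; it is consistent only as
  instrument precision grows.
* Delta-method intervals for mediated proportions are first-order and
  undercover when the total effect is imprecise.
* Log-OR effects are non-collapsible: direct + indirect equals the
  total only approximately, and only for rare outcomes; the mediation
  benchmarks use prevalence 5%.
* MR-PRESSO, mode-based estimators, contamination-mixture methods,
  LD-aware modelling and proxy-SNP lookup are out of scope.
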