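---
title: "Models and methods in dualfactor"
author: "dualfactor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dualfactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualfactor)
```

`dualfactor` analyses mental-health item batteries in which three-category
ordinal symptom items (internalising and externalising domains) are measured
together with continuous wellbeing ratings. This vignette documents the
statistical model, the estimator, the numerical choices, and the design
decisions that were genuinely open — in enough detail that a maintainer can
judge each one.

## The latent-response model

Every item is assumed to measure a linear combination of latent factors. An
ordinal item $j$ is a discretised latent response
$y_j^* = \lambda_j^\top \eta + \varepsilon_j$, observed as category $c$ when
$y_j^*$ falls between thresholds $\tau_{j,c-1}$ and $\tau_{j,c}$; a
continuous item is observed directly with a free intercept and residual
variance. Factors $\eta$ are multivariate normal with correlation matrix
$\Phi$; residuals are normal, independent across items except for a small
set of *residual-correlation pairs* $\theta_{ij}$ representing shared
wording or content.

Identification follows the delta-style convention for categorical CFA: all
factor variances are fixed at 1, all loadings free, factor means 0 in
single-group models, and each ordinal latent response has unit total
variance with no free residual variance. Under this convention the implied
correlation of two items is $\lambda_i^\top \Phi \lambda_j + \theta_{ij}$,
and the degrees-of-freedom arithmetic (statistics = two thresholds per
ordinal item + mean and variance per continuous item + all pairwise
correlations; parameters = free loadings + factor correlations + residual
correlations + continuous intercepts and residual variances + thresholds)
reproduces, exactly, the published df of every structure the package builds:
145 for the three-factor correlated model on the 19-item battery, 129 for
the classical bifactor, 133 for S-1 with the wellbeing specific factor
removed, 138 for S-1 with the internalising specific factor removed, and 113
/ 121 for the reduced models obtained after dropping non-invariant items.
We therefore treat this convention as *the* convention for such analyses.
An implied ordinal residual variance $\le 0$ is a Heywood condition and is
reported as such.

### The four structures

* **Correlated factors** — one factor per domain, free correlations; the
  most parsimonious representation of "related but distinct" constructs.
* **Classical bifactor** — one general factor plus one orthogonal specific
  factor per domain; every item loads twice. Fits well almost by
  construction, which is precisely why it must not be accepted on fit
  alone.
* **S-1** — a bifactor with one domain's specific factor removed; that
  domain's items then define the general factor, giving it a well-defined
  interpretation (e.g. general internalising distress when the
  internalising specific factor is removed).
* **Instrument CFAs** — the correlated-factors pattern restricted to one
  questionnaire, used to screen residual-correlation pairs before the
  joint models are fitted.

## Estimation

### Stage 1: limited-information statistics

Thresholds are estimated as inverse-normal cumulative category proportions.
Correlations are estimated pairwise on pairwise-complete observations:
two-step polychoric (thresholds fixed at the marginal estimates, the latent
correlation maximising the bivariate-normal table likelihood), two-step
polyserial (conditional likelihood of the ordinal response given the
standardised continuous score), and Pearson for continuous pairs. Two-step
rather than joint-ML estimation is the standard choice in
limited-information pipelines and is orders of magnitude faster; its cost is
a potential divergence from full-ML software in the third decimal place.
The one-dimensional likelihood maximisations use `optimize()` with
convergence tolerance 1e-8 and clamp estimates at $|\rho| = .999$ with a
boundary flag.

The bivariate-normal rectangle probabilities at the heart of the polychoric
likelihood are computed by the package's own vectorised kernel: the
single-integral representation with the substitution $r = \sin\theta$, which
removes the endpoint singularity and makes 48-node Gauss–Legendre quadrature
accurate to near machine precision over $|\rho| \le .999$ (validated against
an independent implementation in the test suite at 1e-10).

The asymptotic covariance $\Gamma$ of the stacked statistic vector
(normalised so $\mathrm{cov}(s) = \Gamma/n$) is estimated from
per-observation influence functions of the estimating equations, with
nuisance corrections for the estimated thresholds and for the mean/SD
standardisation in the polyserial case (Jacobians by central differences of
the mean score, step 1e-4). Missingness enters by zeroing the missing
observations' contributions and rescaling each column by $n/n_{obs}$, which
is exact under MCAR. A seeded nonparametric bootstrap of the whole statistic
vector is provided as an independent oracle; the test suite requires
diagonal agreement within 25% at $n = 2000$. Only the diagonal of $\Gamma$
enters point estimation, so robustness requirements concentrate there; the
full matrix enters standard errors and test statistics.

### Stage 2: diagonally weighted least squares

The fit function is
$F(\theta) = (s - \sigma(\theta))^\top W^{-1} (s - \sigma(\theta))$ with
$W = \mathrm{diag}(\Gamma)$, minimised by `nlminb` with box constraints
(factor and residual correlations in $(-.995, .995)$, ordinal scale
parameters positive, continuous residual variances *allowed negative* so
that the negative-residual-variance policy can observe them). Start values:
loadings .5 (general and domain factors) / .3 (specific factors), scaled by
the sample SD for continuous items; zero correlations; thresholds, means and
variances at their sample values. Convergence is declared on `nlminb`'s
relative-convergence criterion or an interior numeric gradient below 1e-3;
otherwise up to three seeded jittered restarts are attempted. A warm
restart from the first optimum is always run, which escapes the shallow
plateaus a quadratic-form objective can produce.

Two small regularisers stabilise empirically under-identified regions
without affecting identified estimates: a smooth penalty
($100\,(.005 - v)^2$ below $v = .005$) keeps implied ordinal residual
variances out of the inadmissible region, and a minuscule ridge
($10^{-3}\sum \lambda_s^2$) on *specific-factor* loadings selects the
minimum-norm solution along the flat ridges that arise when a specific
factor's loadings are truly near zero — the situation the vanishing-factor
diagnostic exists to detect. Without the ridge a global optimiser drifts
along such a ridge until one loading sits at the admissibility boundary
while its siblings collapse, which corrupts ECV; with it, identified
specific loadings shift by order 1e-4, far below reported precision. No
other parameter is penalised, so the 4-item brute-force oracle agreement at
1e-4 in the test suite is unaffected.

The test statistic is the scaled-and-shifted (mean-and-variance adjusted)
form $T^* = a\,nF + b$ with $a = \sqrt{df/\mathrm{tr}[(U\Gamma)^2]}$ and
$b = df - a\,\mathrm{tr}(U\Gamma)$, where
$U = W^{-1} - W^{-1}\Delta(\Delta^\top W^{-1}\Delta)^{-1}\Delta^\top W^{-1}$
is the residual projector and $\Delta = \partial\sigma/\partial\theta$
(central differences at the optimum). This matches first and second moments
of a $\chi^2_{df}$ reference. A mean-only scaled variant is available behind
`adjust = "mean"` for sensitivity checks. Standard errors are sandwich
estimates using the full $\Gamma$. Fit indices use the conventional
independence baseline (zero correlations, free margins), which for this
estimator has a closed form; RMSEA uses $n - 1$ in its denominator (both
$n$ and $n-1$ reproduce the printed three-decimal values we anchor on, so
the choice is cosmetic) and its 90% CI inverts the noncentral-$\chi^2$
distribution at probabilities .95/.05.

Nested models are compared with a second-order scaled difference: the raw
difference $n F_0 - n F_1$ is rescaled by the traces of
$(U_0 - U_1)\Gamma$, referred to $\chi^2$ with $df_0 - df_1$ degrees of
freedom; a negative scaled difference (a known pathology of scaled
statistics) is reported as 0 with a warning. Modification indices are robust
univariate score tests (1 df) of fixed residual correlations, with the
score variance computed from $\Gamma$ so that the null reference is
$\chi^2_1$ even under diagonal weighting.

Instruments whose items are all continuous (the wellbeing scale alone) are
fitted by normal-theory ML on means and covariances, the natural estimator
there; its modification indices are numeric score tests on the ML
discrepancy.

## Measurement invariance and covariates

The three-step multigroup scheme: (1) per-group baselines; (2) a
*configural* model — same structure, all loadings/thresholds/intercepts free
per group, scale parameters fixed at 1 and factor means at 0 in both groups;
(3) a *scalar* model — loadings and thresholds/intercepts equated in tandem,
group-2 factor means and ordinal scale parameters freed. These
identification details are the conventional delta-parameterisation scheme;
they make the configural df exactly the sum of the single-group dfs, which
the tests assert. When the scalar-vs-configural scaled difference is
significant (default level .05), the partial-invariance search iteratively
frees the whole loading+threshold block of the item with the largest block
modification index (a rank-truncated joint score test — the block is
rank-deficient by one because the freed item's scale parameter spans one
direction), refitting until the difference test is non-significant or a cap
(default 5 items) is hit; ties break towards the lower item index. Freed
ordinal items have their group-2 scale parameter re-fixed at 1 for
identification.

A negative continuous residual-variance estimate that is *non-significant*
is refixed at zero and the fix recorded; a *significant* one raises an
error, since it signals misspecification rather than sampling noise.

Associations of the latent factors with binary covariates are estimated by
extending the model with regressions of every factor on one covariate at a
time (a MIMIC structure): the covariate enters the statistic vector as an
exogenous observed variable with free mean and variance, and the
ordinal-covariate correlations use the conditional (polyserial) likelihood,
which remains consistent for binary regressors because the latent response
is conditionally normal given the covariate. Raw and standardised
coefficients are reported; the standardisation uses
$\mathrm{sd}(\eta) = \sqrt{1 + \gamma^2\mathrm{var}(x)}$ with unit
disturbance variance.

## The synthetic-data generator

The generator emulates the survey design the package targets: 9
internalising + 6 externalising three-category items (one reverse-coded,
emitted re-reversed so its loading is positive), 4 continuous wellbeing
items on 0–10, school clustering, binary gender and ever-free-school-meals
covariates, and item-level MCAR missingness with per-item rates spread over
[.006, .026]. Factor scores decompose as
$\eta = \sqrt{\delta}\,c_{k} + \sqrt{1-\delta}\,u_i$ with cluster and
individual components both drawn from $\Phi$, so the factor correlations are
preserved exactly while a share $\delta$ (default .03) of each factor's
variance is between clusters — implying item-level intraclass correlations
of roughly $\lambda^2\delta$, i.e. .004–.03 for the default loadings,
inside the range such school surveys report.

Defaults that the design constraints do not pin down are package
assumptions, chosen once to be realistic for population screening data and
not revisited:

* **Loadings** fixed (not per-run random) between .43 and .80 per domain —
  the only printed constraint on such batteries is that all loadings clear
  ~.43.
* **Thresholds** at cumulative probabilities (.55, .90) for symptom items —
  a marked floor effect, with "never" the modal answer — and symmetric
  (.25, .75) for the re-reversed calm item.
* **Continuous wellbeing items**: mean 7.0, SD 1.5 on the 0–10 scale,
  clipped to the scale bounds (≈2% of draws clip, a negligible moment
  distortion), giving the right-skewed distribution wellbeing ratings show.
* **Residual pairs** (int1,int3), (int5,int6), (int7,int8) at .20–.25 and
  (wb1,wb3) at .26 — the wording-overlap pairs of the emulated instruments.
* **Covariate effects** on factor means: gender (girl = 1) +.19
  internalising, −.38 externalising; income (ever-FSM = 1) +.36
  externalising, +.08 internalising, −.08 wellbeing. Signs follow the
  well-replicated epidemiological pattern (externalising higher in boys and
  low-income groups; wellbeing weakly related to either); magnitudes are
  assumptions. `covariate_effects = FALSE` zeroes them for
  null-calibration experiments.

What the generator deliberately does **not** emulate: non-ignorable
missingness, longitudinal structure, more than three ordinal categories,
item-level differential functioning beyond covariate mean shifts, and
non-normal latent distributions. Passing tests therefore demonstrate
internal consistency of the estimator chain under the latent-normal model,
not robustness to the ways real survey data violate it.

## Numerical choices and degenerate inputs

* Bivariate-normal kernel: 48-node Gauss–Legendre after sin-substitution;
  cell probabilities floored at 1e-300 inside logs.
* Polychoric/polyserial: `optimize()` tolerance 1e-8; boundary clamp at
  .999 with a warning flag; a cumulative category proportion of 0 or 1
  interior to the scale is an error naming the item.
* DWLS: `nlminb` with `rel.tol` 1e-12, warm-restart polish, up to 3 seeded
  jittered restarts; the information matrix is ridged by 1e-10 of its mean
  diagonal before inversion (bifactor fits on near-unidimensional data are
  empirically singular).
* Score-test blocks use a rank-truncated pseudo-inverse (eigenvalues below
  1e-10 of the maximum are treated as null directions).
* A continuous item whose observed values all lie in {1, 2, 3} is rejected
  as mislabelled before estimation; ordinal items with values outside
  {1, 2, 3} likewise.
* Report rounding is 3 decimals; all randomness is seed-derived and every
  pipeline stage is deterministic given (data, config).

## Problem sizes used by the validation suite

The test suite exercises the full 19-item battery where exactness matters
(df accounting, population-moment fixed points, the n = 2000 recovery study
averaged over 10 seeds) and scaled-down 4–15-item versions of the same
machinery for the calibration studies (200-replicate type-I error of the
scaled difference test at n = 1000; 200-replicate scalar-invariance null
calibration at n = 1600 split into two groups; 10-replicate planted
non-invariance and planted-residual-pair detection). These sizes were chosen
so that each property is tested with sampling error well below the margin it
asserts.

## Known limitations

* Standard errors and test statistics are *not* adjusted for clustering;
  with factor-level ICCs around .03 the unadjusted statistics are mildly
  liberal. The ICC computation is provided so users can judge.
* The exact scaling constants of proprietary WLSMV implementations are not
  public; the adjusted statistic here matches their modern scaled-shifted
  form in construction, and real-data χ² values should be expected to agree
  in simulation-recovery terms, not digit-for-digit.
* Two-group invariance only; metric-only (loadings-only) invariance is not
  offered as a separate level because thresholds and loadings of ordinal
  items are not separately identified in any useful sense under the delta
  convention.
* ECV on a fitted bifactor is only as meaningful as the fit; the
  vanishing-factor diagnostic should be consulted alongside it.
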