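---
title: "Methods: Bayesian geo-additive mapping of overweight/obesity prevalence"
author: "geoadd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian geo-additive mapping of overweight/obesity prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Demographic and Health Surveys (DHS) measure height and weight for women
of reproductive age (15–49 years) alongside socio-demographic covariates
and the state of residence.  In settings undergoing the nutritional
transition, overweight and obesity co-exist with widespread
under-nutrition, and their prevalence varies strongly across regions.  The
question this package addresses is: *how does the odds of being
overweight or obese vary across states, after accounting for
individual-level risk factors — and which states carry excess risk that
those factors do not explain?*

The outcome is binary.  BMI (kg/m²) is categorised by the WHO bands —
underweight below 18.5, normal weight 18.5 to below 25, overweight 25 to
below 30, obese 30 and above — and the analysis contrasts overweight/obese
(`y = 1`, BMI ≥ 25) with normal weight (`y = 0`), after excluding
underweight women.  The upper boundaries are implemented half-open
(`[18.5, 25)`, `[25, 30)`), treating printed band labels such as "24.9"
as display rounding of the WHO convention.  Exclusions are applied in a
fixed order — underweight first, then incomplete covariate records
(complete-case analysis) — so the exclusion ledger is reproducible
regardless of the missingness pattern.

## The geo-additive model

For woman $i$ living in state $s_i$,

$$\operatorname{logit} P(y_i = 1) \;=\; x_i'\beta \;+\; f_1(\text{age}_i)
\;+\; f_2(\text{age}^{partner}_i) \;+\; u_{s_i} \;+\; v_{s_i},$$

with

* **Fixed effects** $\beta$: treatment-coded dummies for education (own
  and partner's), urban/rural residence, religion, wealth quintile and
  ethnicity, with the conventional reference levels (no education,
  rural, Catholic, poorest, Ekoi; Yobe for state contrasts in the
  marginal model).  Prior: diffuse Gaussian, variance $10^6$ —
  effectively flat while keeping every full conditional proper.
* **Smooth age effects** $f_1, f_2$: penalised cubic B-splines
  (P-splines) with $K = 20$ basis functions on equidistant knots over the
  observed range, and a second-order random-walk (RW2) prior, i.e. a
  Gaussian prior with precision $\tau_f^{-2} D_2'D_2$ where $D_2$ is the
  second-difference matrix.  $K = 20$ with RW2 is the long-standing
  default of structured additive regression software for effects of this
  smoothness; the penalty makes the effective degrees of freedom
  data-driven, so results are insensitive to $K$ once it is generous.
* **Structured spatial effect** $u$: intrinsic CAR / Gaussian Markov
  random field prior with precision $\tau_u^{-2} Q$, $Q = D - A$ (degree
  minus adjacency) built from the state adjacency graph.  This shrinks
  each state toward the mean of its neighbours.
* **Unstructured spatial effect** $v$: iid $N(0, \tau_v^2)$ per state,
  capturing region-level heterogeneity with no spatial pattern.  The
  *total* residual spatial effect mapped downstream is $u_s + v_s$; both
  components are on by default because only their sum is well identified
  and it is the quantity of epidemiological interest.
* **Hyperpriors**: every variance gets an inverse-gamma
  IG(a = 0.001, b = 0.001) prior, the conventional diffuse choice in this
  model family; both constants are exposed in `mcmc_config()`.

### Inference: Pólya-Gamma Gibbs sampling

The logistic likelihood is augmented with Pólya-Gamma latent variables
$\omega_i \sim \mathrm{PG}(1, \eta_i)$, which makes every coefficient
block conditionally Gaussian: the block update solves
$(X_b'\Omega X_b + P_b)\,\gamma_b = X_b'(y - \tfrac12 - \Omega\,
\eta_{-b})$ and adds Cholesky-factored noise.  Variances are drawn from
their conjugate inverse-gamma conditionals
$\mathrm{IG}(a + \mathrm{rank}(P)/2,\; b + \gamma'P\gamma/2)$.  The
PG(1, z) draws use Devroye's exact alternating-series rejection sampler,
implemented in C++ on R's RNG stream, so a chain is bit-reproducible from
its seed and needs no tuning or Metropolis acceptance monitoring.  This
augmented Gibbs scheme targets the same posterior as the
IWLS–Metropolis samplers used in classical structured-additive-regression
software, but is exactly conjugate.

**Identifiability.**  The RW2 prior is invariant to adding a constant to
a smooth, and the ICAR prior to adding a constant per connected
component, so levels are aliased with the intercept.  After every
iteration each smooth is re-centred to mean zero over the observed
covariate values — exactly, via the B-spline partition of unity (row sums
are 1, so subtracting a constant from all coefficients shifts the curve
by that constant) — and each spatial component is centred to sum to zero,
with the removed means transferred into the intercept.  For a connected
graph the transfer is exact (the linear predictor is unchanged); for a
disconnected graph the observation-weighted mean is transferred, which
leaves small per-component level differences absorbed by $u$ itself.
Both shipped geographies (the 31-region Nigeria graph and the test
lattices) are connected.

**Defaults.**  12,000 iterations, 2,000 burn-in, thinning 10 (1,000 saved
draws).  On the synthetic fixtures the intercept's effective sample size
under this configuration is several hundred and Geweke z-scores are
within ±3 for essentially all parameters; the defaults follow the
conventions of the model family rather than any claim of optimality, and
shorter chains are used for small fixtures in tests.

### Posterior summaries

* **POR tables**: the posterior odds ratio is reported as
  $\exp(\text{posterior mean of the log-odds effect})$ — the convention
  of structured-additive-regression software — with equal-tailed credible
  regions $\exp(q_{\alpha/2}), \exp(q_{1-\alpha/2})$ (not HPD; order
  statistics are exact and monotone under the log transform).  The
  alternative summary $\mathrm{E}[\exp(\cdot)]$ is available behind a
  flag; by Jensen's inequality it is always larger.  Tables print two
  decimals.
* **Nonlinear curves**: pointwise posterior mean and equal-tailed band of
  the centred smooth on a grid, at the 80% level conventional for these
  displays; no extrapolation outside the observed covariate range.
* **Maps**: each state's total effect $u_s + v_s$ is summarised by its
  POR and categorised at a nominal level (default 80%): *positive*
  (higher odds, black) if the credible region lies above 0, *negative*
  (lower odds, white) if below, *none* (grey) otherwise.  Because a 95%
  region contains the 80% region, significance at 95% implies
  significance at 80%; the categoriser is monotone in the level by
  construction.  The 80% default follows the figure convention of this
  literature; 95% is available via the `level` argument.  Annotated
  GeoJSON export colours the POR map on a red (high) to green (low) ramp.

## The marginal model

For comparability with conventional DHS analyses the package also fits a
standard maximum-likelihood logistic regression with *grouped* ages
(respondent ≤25 / 26–35 / 36–49; partner ≤30 / 31–40 / 41+) and state
dummies with Yobe as reference (the state with the lowest crude
prevalence).  The fit is by IRLS iterated to a deviance change below
1e-8 (with step-halving, so the deviance is monotone non-increasing; a
full-Newton step can otherwise overshoot near separation), Wald 95%
intervals ($\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ — "95% CI" is
unspecified in the source literature and Wald is the convention in DHS
work), and explicit separation (|coef| > 15) and collinearity
diagnostics.  All covariates enter one model simultaneously; the
alternative (per-block adjustment) is not used because nothing in the
source material indicates it.

## The synthetic-data generator

DHS microdata are access-restricted, so the pipeline is validated on
synthetic records whose generative model mirrors the fitted one — this is
what makes every downstream stage testable with known truth.

* **Covariates** are drawn independently from the published whole-sample
  marginal percentages (education, partner education, residence,
  religion, wealth, ethnicity); ages are rounded truncated normals
  matching the published means and SDs (29.3 ± 7.1 on 15–49 for
  respondents; 40.9 ± 12.8 on 15–95 for partners); states are uniform
  over the graph by default.  Joint covariate dependence (e.g.
  wealth–education correlation) and household clustering are deliberately
  not modelled: the validation targets are regression parameters, not
  survey design.
* **Effects**: fixed-effect log-odds default to the logs of the published
  adjusted odds ratios; the default smooths are
  $0.9\sin(\pi(a-15)/60)$ (maximum at age 45) and
  $0.8\sin(\pi(a-15)/110)$ (maximum at 70), qualitatively matching the
  reported nonlinear age effects; spatial effects are drawn from the
  ICAR distribution (spectral decomposition of $Q$, zero-sum per
  component) plus centred iid noise.  The intercept is calibrated by
  subtracting the mean covariate effect from logit(0.209), so the default
  scenario's overall prevalence sits near the published 20.9%; with a
  nonlinear link this first-order calibration is approximate (realised
  prevalence is typically within a point or two).
* **BMI values** are drawn *uniformly inside the destination category*
  (underweight [15, 18.5) with probability 0.12, matching the published
  underweight share; otherwise [25, 35) when the Bernoulli outcome is 1,
  [18.5, 25) when 0).  Categorisation is therefore exactly invertible —
  by design the generator validates the categoriser's boundaries, not the
  shape of a realistic BMI distribution.

What passing recovery tests do show: the sampler targets the right
posterior (it matches deterministic quadrature and the MLE where those
are available), the spatial ranking of regional effects is recovered
(rank correlation ≥ 0.8 at n = 10,000 on a 36-region lattice with
$\tau^2_{spat} = 0.5$), the age-effect peak is located within a few
years, and credible intervals attain near-nominal coverage.  What they do
not show: robustness to survey weights, clustered sampling, covariate
dependence or BMI measurement error, none of which the generator
emulates.

## Numerical choices and degenerate inputs

* B-spline knots are equidistant with exact range endpoints (a cumulative
  `seq()` can strand `max(x)` just outside the admissible span by a
  rounding ulp); constant covariates are rejected.
* The spline full-conditional precision adds a 1e-8 ridge: the RW2
  penalty has rank $K-2$ and the data term, while positive definite for
  non-degenerate designs, can be near-singular when a basis function
  covers few observations.
* ICAR simulation uses the spectral pseudo-inverse; eigenvalues below
  $10^{-10}\lambda_{max}$ are treated as null space.
* Ties in the Mann–Whitney test use midranks with tie-corrected variance
  and continuity correction; the exact null is enumerated when the
  smaller sample has ≤ 8 observations and no ties (exhaustive enumeration
  is cheap there; the switch point is a convention, not a claim).
* Pearson chi-square is computed without continuity correction; zero
  marginals are an error rather than an NaN.
* Crude odds ratios fail on zero cells unless the Haldane–Anscombe 0.5
  correction is requested explicitly.
* An "Oye" state label is accepted as an alias of "Oyo" (and
  "Enungu/Ebonyi" of "Enugu/Ebonyi", "Crossriver" of "Cross River"):
  print variants seen for these regions.  The shipped Nigeria geography
  uses the 31-region aggregation (30 pre-1996 states + Abuja, six
  post-1996 split pairs merged), constructed at graph build time so model
  code never re-aggregates.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data:
the recovery experiment uses a 6×6 lattice with n = 10,000 and a
4,000-iteration chain (1,000 burn-in, thinning 3); the quadrature
comparison uses 30,000 iterations on 10 observations; coverage checks use
50 replicates of n = 800 with short chains; the demonstration pipeline
runs n = 5,000 on the lattice ("small") or n = 25,000 on the Nigeria
graph ("full", 12,000 iterations).  These sizes were chosen so a complete
validation runs comfortably on a laptop while leaving Monte-Carlo error
well inside every asserted tolerance.

## Known limitations

* No survey weights or design effects: the source analyses are
  unweighted, and the package follows them.
* Single-chain inference; between-chain diagnostics (R-hat) are not
  implemented (ESS and Geweke checks are).
* The marginal and geo-additive models share the complete-case analysis
  set; no imputation of partner covariates for unpartnered women.
* Published posterior odds ratios from the restricted microdata are not
  reproducible and are used only as effect-size anchors for the
  generator; validation is against oracles and simulation truth instead.
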