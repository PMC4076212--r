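# geoadd

Bayesian geo-additive binary regression for mapping overweight/obesity
prevalence from DHS-style survey records.

## The problem

Demographic and Health Surveys measure height, weight and
socio-demographics for women aged 15–49, indexed by state of residence.
In populations undergoing the nutritional transition, overweight/obesity
prevalence varies strongly across regions, and the question of interest
is how much of that variation individual-level risk factors explain —
and which states carry residual excess risk.  `geoadd` implements the
full analysis chain for this question: WHO BMI categorisation and binary
outcome construction, descriptive contingency tables with chi-square and
Mann–Whitney tests, maximum-likelihood logistic regression, and the
Bayesian geo-additive model at the core:

$$\operatorname{logit} P(y_i=1) = x_i'\beta + f_1(\mathrm{age}_i)
 + f_2(\mathrm{age}^{p}_i) + u_{s_i} + v_{s_i}$$

where `y` is overweight/obese (BMI ≥ 25) vs normal weight, `β` are fixed
effects of education, residence, religion, wealth and ethnicity, `f₁, f₂`
are P-spline smooths (20 cubic B-splines, second-order random-walk
priors) of respondent and partner age, `u` is a structured state effect
with an intrinsic CAR (Gaussian Markov random field) prior on the state
adjacency graph, and `v` is an iid unstructured state effect.  All
variances get IG(0.001, 0.001) hyperpriors.  Inference is exact
conjugate Gibbs sampling via Pólya-Gamma data augmentation (Devroye's
sampler, implemented in C++ on R's RNG, so chains are reproducible from
a seed).  Posterior summaries are the field's standard outputs: posterior
odds-ratio (POR) tables with credible regions, nonlinear-effect curves
with 80% bands, and three-colour posterior-probability maps of the total
spatial effect `u + v`, exportable to GeoJSON.

Because DHS microdata are access-restricted, the package includes a
synthetic survey generator with known ground truth (fixed effects,
smooth age effects peaking near 45/70 years, ICAR spatial effects, a
12% underweight stratum) that emulates the 2008 Nigerian survey
conditions; every stage is validated against it and against independent
oracles (grid quadrature, maximum likelihood, enumeration).

## Worked example

```r
library(geoadd)

## published worked example: prevalence arithmetic from printed counts
tab <- published_counts()
w <- tab[tab$variable == "wealth", ]
crude_prevalence(sum(w$n_case),
                 sum(w$n_control) + attr(tab, "underweight_excluded"))
#> [1] 20.9        # combined overweight/obesity prevalence, full sample
sum(w$n_case) + sum(w$n_control)
#> [1] 24614       # analysis set after excluding 3,353 underweight women
rich <- w[w$level == "richest", ]; poor <- w[w$level == "poorest", ]
or <- crude_odds_ratio(rich$n_case, rich$n_control, poor$n_case, poor$n_control)
format_or(or$or, or$lower, or$upper)
#> [1] "6.64 (6.00, 7.36)"   # crude OR, richest vs poorest quintile

## synthetic end-to-end run with known truth (about a minute)
man <- run_demo(seed = 101, scale = "small")   # 6x6 lattice, n = 5,000
man$spatial_rank_correlation
#> [1] 0.94        # true vs posterior-mean total regional effects
```

The `run_demo()` directory contains the exclusion ledger, descriptive
tables, the marginal OR table, the posterior OR table, smooth-effect
curves, the categorised spatial map (`map_categories.csv`,
`map.geojson`) and a recovery report.  On the full-scale synthetic
Nigeria run (n = 25,000, 12,000 iterations; `analysis/` scripts) the
fitted posterior ORs line up with the generator's effect sizes — e.g.
urban 1.18 (1.10, 1.27), richest wealth quintile 3.58 (3.25, 3.98) — the
state map resolves 9 higher-risk and 9 lower-risk states at the 80%
level, and the rank correlation between true and estimated state effects
is 0.95.

## Analysis scripts

`analysis/01_simulate.R` … `analysis/06_summarize.R` run the whole
pipeline as numbered stages (simulate → preprocess → describe → marginal
fit → geo-additive fit → posterior summaries), writing tables under
`results/` and bulky intermediates under `scratch/`.  Each stage reads
the previous stage's files, so stages can be re-run individually.

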