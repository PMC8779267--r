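---
title: "Models and methods: from host rearing treatments to parasitoid yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from host rearing treatments to parasitoid yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parayield)
```

## The problem

Mass rearing of hymenopteran egg parasitoids such as *Paratelenomus
saccharalis* needs a steady supply of host eggs. Its host, the kudzu bug
*Megacopta cribraria*, enters reproductive diapause under short photoperiods,
so field-collected adults stop laying exactly when colonies need augmenting.
Two interventions can restart oogenesis: an artificial long-day photoperiod
(16L:8D) and topical application of the juvenile-hormone analog pyriproxyfen
(0.1% or 1.0% in acetone). Both carry costs — pyriproxyfen shortens adult
life and lowers egg viability — so the question of practical interest is the
*net* effect on parasitoid yield: eggs produced per replicate of 20 host
females, times the probability an exposed egg yields an adult parasitoid.

`parayield` implements the full analysis chain for this factorial rearing
experiment (2 field collections x 2 photoperiods x 3 chemical treatments x
4 replicate containers of 20 females + 10 males):

1. censored Weibull accelerated failure-time (AFT) models of female
   survival, with hazard-ratio conversion and Kaplan–Meier summaries;
2. negative-binomial (and hurdle) regression of container egg totals, with
   term-level F tests, estimated marginal means (EMMs) and Tukey-adjusted
   compact letter displays;
3. clutch-size-weighted binomial logistic regression of egg eclosion and
   parasitoid emergence;
4. a Monte-Carlo propagation of fecundity and emergence uncertainty into
   parasitoid yield per treatment.

Because the underlying insect-level data are not publicly released, the
package also ships a synthetic-data generator calibrated to the reported
model estimates, so that every stage is exercised end to end and
generate-and-refit recovery can be tested.

## Survival: Weibull AFT

Female death times are modeled as `log T = mu + x beta + sigma W` with `W`
standard minimum-Gumbel, i.e. `T` is Weibull with scale `exp(mu + x beta)`
and shape `1/sigma`; right censoring at the follow-up horizon enters the
likelihood through the survivor function. Fitting is delegated to
`survival::survreg` with a tightened tolerance; the package adds the
intercept-only likelihood-ratio test (`aft_lrt()`) and the hazard-ratio map
`exp(-beta/sigma)` with delta-method intervals computed from the joint
covariance of `(beta, log sigma)` (`hazard_ratios()`).

Referent handling deserves a note: the survival fits use the short-day +
acetone cell as the referent (the long-day indicator carries a coefficient),
while the egg-production fits use long-day + acetone. Every sample object
carries its `referent` explicitly and all outputs report it, so neither
convention is hard-coded.

Kaplan–Meier curves use the product-limit estimator with Greenwood standard
errors; the median is the earliest time survival reaches 0.5, and its
confidence interval comes from inverting the log(−log) pointwise band — the
default of standard survival software, adopted here because it is what the
original analysis tooling would have produced. Deaths precede censorings at
tied times. An all-censored group is reported with survival 1 and an `NA`
median, flagged rather than refused.

## Egg production: negative binomial and hurdle

Container egg totals are overdispersed counts; the headline model is a
log-link negative-binomial GLM (`MASS::glm.nb`, profile-ML for theta) with
additive chemical and photoperiod indicators — no interaction term, matching
the three-coefficient structure of the reported tables (an interaction can
be added through the design matrix but is off by default). Short-day acetone
containers lay nothing at all; a cell of repeated zeros puts the NB
likelihood on an under-dispersion boundary, so `fit_nb_glm()` detects that
situation up front and raises a typed error recommending the hurdle model.
`fit_hurdle_nb()` factorizes the likelihood into a binomial-logit zero
process and a zero-truncated NB for the positive totals (hand-written
maximum likelihood on `(beta, log theta)`, since no installed package
provides truncated-NB regression); the joint log-likelihood is exactly the
sum of the parts, which the tests assert. A cell that is all-zero separates
the zero part perfectly, in which case a Firth-penalized (Jeffreys-prior)
logit is substituted and flagged.

Term-level F tests refit the model without a term's columns, holding theta
at the full-model estimate, and refer `(deviance drop/df1)/dispersion` to an
F distribution with `df2 = n - p`, the Pearson dispersion in the
denominator. The suite checks this recipe's type-I error empirically (1000
null simulations; the rate must fall in 0.03–0.07 at alpha 0.05).

EMMs are computed by direct contrast algebra: cell linear predictors
`L beta`, link-scale covariance `L V L'`, t intervals with `df = n - p`
(asymptotic-normal intervals would be too narrow at 4 replicates per cell),
back-transformed through the log link. For hurdle fits `emm_counts()` offers
the unconditional mean (positive probability x truncated mean) and the
conditional mean of an egg-producing container; the yield stage uses the
conditional mean, because the reported egg-model intercept equals the raw
cell mean of the referent (705/4 = 176), showing the original yield
calculation was parameterized by the count process, not a zero-deflated
mean.

Tukey-adjusted pairwise contrasts use the studentized-range distribution
(`ptukey`) on the link scale with the fit's `df2`; letters come from the
insert-and-absorb compact-letter-display algorithm. Adjusted p-values are
floored at the unadjusted ones, and the tests verify the letter/contrast
consistency property in both directions, plus agreement of the adjusted p
with direct numerical integration of the studentized-range CDF.

## Egg viability: weighted binomial logit

Each clutch contributes `n_success` of `n_eggs` Bernoulli outcomes; the
clutch size is the binomial weight, which makes the clutch-aggregated fit
exactly equal to an egg-level Bernoulli fit (asserted in the tests). The
model is a cell-means logit over the five treatment cells with eggs (the
short-day acetone cell produced none). A cell whose pooled outcome is 0% has
no finite MLE; the fit switches to the Firth penalty (flagged), and the EMM
table reports the raw 0 with a one-sided rule-of-three interval
`(0, 1 - alpha^(1/n))` rather than dropping the cell. Its letter comes from
the penalized fit — the penalty shrinks the boundary cell enough to keep its
contrast with the referent meaningful instead of drowning it in an infinite
standard error.

## Parasitoid yield: Monte-Carlo propagation

For each treatment cell, one simulation draw is

* an egg total from the log-normal sampling distribution of the fitted egg
  mean (normal on the log link), and
* an emergence probability from the logit-normal sampling distribution of
  the fitted emergence rate (normal on the logit link),

and their product is the parasitoid yield of one 20-female replicate; 2000
draws per cell. The two draws are independent — they estimate parameters of
disjoint experiments (container fecundity vs clutch exposure assays). The
draw distributions are the models' estimate sampling distributions, not
predictive distributions; point-mass inputs already reproduce the reported
yield means to within rounding, which is the diagnostic that fixed this
choice. (A parametric-bootstrap variant can be obtained by passing
predictive-scale SEs into `simulate_yield()`; nothing in the pipeline
depends on the normal-on-link assumption beyond the two `r*` calls.)

In preset mode (`yield_preset()`), the egg link means come from the reported
September coefficients. The reported tables give coefficient SEs but not
their covariance, so a non-referent cell's linear-predictor SE cannot be
reassembled exactly: summing SEs in quadrature would ignore the negative
intercept–coefficient covariance of a treatment-contrast parameterization
and overstate the spread. Instead every cell is assigned the intercept's SE
(0.107): the design is balanced with four containers per cell and the
response is approximately homoscedastic on the log scale, so each cell mean
is estimated with roughly the referent's precision. Emergence SEs are
reported per cell, so they transfer directly (delta method to the logit
scale).

`summarize_yield()` reports per-cell means, empirical 95% quantile
intervals, percent increases over the referent cell, and letters from a
gamma GLM with log link fitted to the draws (yields are positive and
right-skewed; the original comparison is described only as "a generalized
linear model", and the gamma family is the natural choice for that shape)
with Tukey-adjusted contrasts.

A caveat that the acceptance checks surface deliberately: the reported
coefficient tables, taken at face value, put the two long-day pyriproxyfen
yields about 5% apart (≈118 vs ≈113 parasitoids), and 2000 draws resolve a
5% difference as significant, so those two cells do *not* share a letter
here, and the percent increase of the 0.1% treatment over the acetone
control computes to ≈92% rather than the reported ≈87%. Reproducing the
reported 114.3 vs 113.7 equivalence requires unrounded fitted estimates that
were not published. The package reports what the published coefficients
imply.

## The synthetic-data generator

The generator inverts the three analysis models with parameters equal to the
reported estimates (`rearing_preset()`):

* **Death times**: Weibull draws from the AFT surface; males receive the
  same surface as females (they were not analyzed; the analysis stages drop
  them at ingest). Censoring horizon 60 days by default, the span of the
  reported survival curves.
* **Egg totals**: hurdle NB per container — short-day acetone cells have
  zero probability 1 (they never laid), all other cells draw zero-truncated
  NB totals. The NB dispersion is not reported; the preset uses theta = 25,
  back-calculated from the reported coefficient SEs via
  `Var(log cell mean) ≈ (1/theta + 1/mu)/4` (theta = 5, say, would give
  coefficient SEs near 0.3 where 0.107–0.140 are reported, and would break
  the reported significance pattern of the F tests). Theta remains an
  exposed free parameter.
* **Clutch structure**: container totals are partitioned into clutches with
  iid zero-truncated Poisson(23) sizes, the last clutch taking the
  remainder; 23 eggs per clutch is the ratio of exposed eggs to exposed
  clutches in the viability assay. Clutch structure only feeds the
  proportion models' weights, so finer oviposition dynamics are not
  modeled.
* **Clutch outcomes**: binomial in the clutch size with the per-cell
  reported eclosion/emergence probabilities; parasitism clutches are
  conditioned to at least 15 eggs (the exposure assay's minimum). The
  default number of assayed clutches per cell is the reported per-cell egg
  total divided by 23, which reproduces the ~69 exposed clutches of the
  original assay. Viability assays existed only for the September
  collection, so the August preset carries empty probability maps.

What the generator does **not** emulate: diapause physiology or its
termination kinetics, pharmacokinetics of the topical dose, temperature
effects, within-day oviposition timing, container-level random effects
beyond NB dispersion, or any correlation between a female's survival and
her fecundity. Passing tests therefore demonstrate that the analysis chain
recovers the parameters of data *with the assumed structure* — not that the
models are adequate for the original raw data. One known internal tension of
the reported numbers is visible here: the August AFT parameters imply a mean
of ≈25 female-days within the 60-day horizon, while the reported August
female-day total works out to ≈7.4 per female; the generator follows the
AFT parameters, so its descriptive eggs-per-female-day ratio for August is
smaller than the reported 0.13.

## Numerical choices

* `survreg` and `glm.nb` run at tightened tolerances (1e-11/1e-12); the
  truncated-NB optimizer is BFGS on `(beta, log theta)` initialized from a
  log-linear least-squares fit and a moment estimate of theta, with the
  covariance from the numerical Hessian.
* The Firth penalty is implemented as IRLS with the hat-value
  half-correction on the score; it is engaged automatically on detected
  separation or boundary cells and always flagged in the fit object.
* Ties in KM follow the deaths-before-censorings convention.
* Degenerate contrasts (identical cells) get `t = 0`, adjusted p 1.
* All stage seeds derive from one master seed through a fixed
  linear-congruential step (`child_seed()`), keeping every stage
  independently reproducible and all seeds below 2^31.
* CSV outputs round floats to 4 significant digits; JSON outputs keep full
  precision.

## Validation problem sizes

The test suite validates the chain at these scales, chosen to make
Monte-Carlo tolerances (uniformly 3 standard errors) tight enough to be
meaningful while keeping the suite quick: 10^4 draws for closed-form
generator checks; 100 generate-and-refit survival replicates at ~2000
females; 500 replicate egg-model fits at the experiment's own size (4
containers per cell); ~10^4 eggs per cell for viability recovery; 1000
simulations each for the F-test type-I calibration and the null distribution
of the AFT likelihood-ratio statistic (Kolmogorov–Smirnov against
chi-square); brute-force likelihood oracles on instances of n ≤ 30 agreeing
to 1e-4 (1e-6 for the logit).

## Limitations

* The hurdle zero part is saturated by the design (cells either always or
  never lay), so its coefficients are only weakly identified and the
  Firth-penalized estimates should be read as regularized summaries.
* The F-test denominator uses the Pearson dispersion with theta held fixed;
  with 16–20 residual df this is an approximation, albeit one whose type-I
  error the suite verifies empirically.
* Preset-mode yield SEs depend on the balanced-precision assumption
  described above; the unpublished coefficient covariance cannot be
  recovered from the reported tables.
* The yield simulation propagates fecundity and emergence uncertainty only;
  host survival uncertainty does not enter (by design, matching the original
  computation), and neither does between-replicate biological variation
  beyond what the two sampling distributions carry.
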