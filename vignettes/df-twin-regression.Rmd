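---
title: "DeFries-Fulker twin regression: model, design and validation"
author: "dftwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DeFries-Fulker twin regression: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dftwin)
```

## The method

DeFries-Fulker (DF) analysis is a regression formulation of the classical
twin design. Samples of MZ and same-sex DZ pairs differ systematically in
genetic similarity (relatedness $R = 1$ vs $R = 0.5$) while sharing their
rearing environment, so regressing one twin's outcome on the co-twin's
outcome and its interaction with $R$ separates three sources of variance.
`dftwin` implements three model variants.

The classic equation (`EQ1`):

$$K_1 = b_0 + b_1 K_2 + b_2 R + b_3 (R \times K_2) + e$$

and the revised, mean-centered equation (`EQ2`, the default):

$$K_1 = b_0 + b_1 (K_2 - K_m) + b_2 \left[R \times (K_2 - K_m)\right] + e$$

where $K_1$ is the focal twin's score, $K_2$ the co-twin's score, and
$K_m$ the mean of $K_2$ over the analysis sample. In `EQ2`, $b_1$
estimates the shared-environmental variance share $c^2$, $b_2$ estimates
heritability $h^2$, and the residual $1 - b_1 - b_2$ absorbs the nonshared
environment together with measurement error. (In `EQ1` the same roles are
played by the $K_2$ and $R \times K_2$ coefficients; the main effect of
$R$ is not interpreted.) The correspondence is exact at the population
level: the within-pair outcome correlation is $h^2 + c^2$ for MZ and
$0.5\,h^2 + c^2$ for DZ pairs, so the relatedness-specific co-twin slope
$b_1 + b_2 R$ reproduces both when $b_1 = c^2$ and $b_2 = h^2$. This also
assumes equal outcome means and variances across zygosity groups — the
reason the centered form needs no main effect of $R$.

Measured within-pair differences enter as ENVDIF terms (`EQ3`):

$$K_1 = b_0 + b_1 (K_2 - K_m) + b_2 \left[R \times (K_2 - K_m)\right]
  + b_3\,\mathrm{ENVDIF} + e$$

with $\mathrm{ENVDIF}$ the focal-minus-co-twin difference on a covariate.
$b_3$ is an ordinary regression coefficient in outcome units per covariate
unit, tested with the usual $t$ statistic.

### Double entry and clustered inference

Each pair contributes two rows with $K_1$/$K_2$ (and the ENVDIF sign)
swapped, so every twin is used both as outcome and as predictor. The two
rows of a pair are not independent; ordinary OLS standard errors would be
deflated. `fit_df()` therefore reports Huber-White cluster-robust standard
errors with the pair as the cluster:

$$\widehat{V} = (X'X)^{-1}\Big[\sum_g X_g' u_g u_g' X_g\Big](X'X)^{-1}
  \cdot \frac{G}{G-1}\cdot\frac{N-1}{N-k}$$

with $G$ clusters, $N$ rows and $k$ columns. The small-sample factor is
the CR1 convention of survey-regression software, and tests use a $t$
reference with $G - 1$ degrees of freedom; `cr_type = "CR0"` drops the
factor. Monte Carlo calibration (6 000 replicates of 500 pairs per
zygosity, null ENVDIF covariate) puts the empirical size of the nominal
5% test at 0.051 with ratio mean(SE)/sd(estimate) of 1.00 — the suite's
calibration test reproduces this at 1 000 replicates.

### What the coefficients are — and are not

Variance-share estimates are reported unconstrained. A $c^2$ or $h^2$
outside $[0, 1]$, or a negative residual, is a diagnostic of sampling
error or model misfit and triggers a warning, not truncation; truncating
would hide exactly the information a reader needs.

The ENVDIF coefficient deserves more care. Suppose a covariate $X$ with
variance $v$ raises each twin's latent outcome by $\beta$ per unit, with
independent draws per twin. Because $K_2$ also contains the co-twin's
$\beta X_2$, conditioning on $K_2$ partially adjusts the difference score
away, and the population value of the fitted ENVDIF coefficient is

$$b_3^\ast \;=\; \beta\,\frac{1 + \beta^2 v + \bar r}{2 + \beta^2 v},$$

where $\bar r$ is the row-weighted mean within-pair outcome correlation.
For MZ-only data ($\bar r \to h^2 + c^2 \to$ the within-pair correlation
of the non-covariate part$\,=1$ in the pure-genetic limit) the expression
collapses to $\beta$; in mixed samples small effects are attenuated by
roughly $(1 + \bar r)/2$. The package's recovery tests therefore check
unbiasedness against this projection (an exact function of second
moments), while the headline recovery check uses the generative $\beta$
with a tolerance wide enough to cover the attenuation. Practically: DF
ENVDIF coefficients are well-defined regression effects of within-pair
differences, but they are conservative estimates of a structural per-unit
effect when that effect operates in both twins.

## The synthetic twin generator

`simulate_twins()` draws each pair's latent outcome as

$$Y^\ast = \sqrt{h^2} A + \sqrt{c^2} C + \sqrt{e^2} E + \textstyle\sum_j \beta_j X_j$$

with $A$ standard normal and correlated 1.0 (MZ) or 0.5 (DZ) within a pair
(the DZ value matching the relatedness coding the estimator assumes — no
dominance or assortative-mating options), $C$ shared, $E$ independent, and
covariates $X_j$ drawn from four families that cover common survey
measurement types: bounded counts (days/week, 0-7), binaries, discretised
proportions, and 4-level frequency ordinals. A Gaussian copula exposes the
within-pair covariate correlation as a parameter; its default is 0, i.e.
co-twins' habits are drawn independently — the least favourable case for
ENVDIF power, chosen because the joint distribution of co-twin habits is
rarely reported and any positive value would be an assertion we cannot
source.

`default_study_config()` freezes the conditions the generator is meant to
emulate: a same-sex adolescent twin subsample of roughly 350 analysable
pairs, 53% of them MZ; ACE shares $h^2 = 0.27$, $c^2 = 0.44$,
$e^2 = 0.29$ for a verbal-ability outcome; and seven derived
nutrition/activity measures whose marginal moments match published
descriptive statistics of such samples (e.g. mean fast-food frequency
2.27 days/week, 25% low vegetable consumption, mean meal-deprivation
proportion 0.24). The insufficient-exercise indicator is derived from the
three activity ordinals rather than drawn independently, preserving its
deterministic relationship to them.

When `percentile_output = TRUE` the outcome is the within-sample
percentile rank, $100 \times (\#\text{strictly lower})/N$ — the convention
of vocabulary-test percentile scores, with ties sharing a value and a
near-uniform marginal (SD $\approx 28.9$). Percentile ranking is a
monotone, nonlinear compression: it preserves order, but variance shares
estimated on the percentile scale are mildly attenuated relative to the
latent scale. Parameter-recovery experiments therefore run on the raw
latent scale (`percentile_output = FALSE`); this is a documented caveat,
not a free choice per experiment.

What the generator does **not** emulate: assortative mating, genetic
dominance, sex-linked or age effects, zygosity misclassification,
covariate measurement error, and any informative missingness (the only
missingness mechanism is uniform whole-pair dropout). Passing recovery
tests under this generator shows the estimator is correct for the model
class it assumes; it cannot show that real twin data satisfy those
assumptions.

## Survey measure construction

`add_measures()` builds seven derived variables from raw items:

* **fast_food** — weekly fast-food days, 0-7, passed through after range
  validation.
* **low_veg** — 1 if none of twelve ate-yesterday vegetable flags is set.
  A record with all observed flags 0 but any flag missing is coded
  missing: consumption cannot be ruled out. (An observed 1 forces 0
  regardless of missingness.) Whether partially observed batteries should
  instead count as 0 is a genuinely open coding question; the stricter
  rule was chosen and is flagged here.
* **meal_dep** — proportion of the 21 weekly meals skipped,
  $((7-b)+(7-l)+(7-d))/21$.
* **low_sport, low_cycle, low_exercise** — activity frequency ordinals
  (0 = not at all … 3 = 5+ times) reverse-coded so higher = less active.
* **insuff_ex** — 1 if total weekly activity bouts fall below five, the
  five-sessions-a-week guideline. The raw items are categories, not
  counts, so a category-to-bout map is required; the default uses interval
  midpoints 0, 1.5, 3.5 and 5 for the open-ended top category. Under this
  map a single top-category item alone (5 bouts) already meets the
  guideline. The map and threshold are arguments, not constants.

Missing inputs propagate to missing outputs throughout — no imputation.
Model fitting then deletes listwise at the *pair* level: if either twin
lacks any variable a model uses, both rows drop, because both $K_2$ and
the ENVDIF scores would be undefined. Reported `N` counts twins (rows),
i.e. twice the pairs.

## Numerical and design choices

* $K_m$ is computed on each model's own post-deletion sample, so each
  fitted model is self-contained and its centered co-twin score has mean
  exactly 0; models with different missingness patterns legitimately
  report different $N$.
* Relatedness is coded 0.5/1.0 (not rescaled to 0/1), so $h^2$ reads
  directly off the interaction coefficient.
* Covariates are never standardised; ENVDIF coefficients stay in outcome
  units per raw covariate unit, and binary covariates yield difference
  scores in $\{-1, 0, 1\}$.
* Single-zygosity data make the design rank-deficient (the interaction
  column collapses into the centered co-twin column); this is detected and
  reported as an error naming the collinear columns rather than silently
  dropping terms. `fit_df()` additionally requires at least two pairs of
  each zygosity.
* Pairs of undetermined zygosity and pairs failing listwise deletion are
  excluded with logged counts.
* All simulation randomness flows from one integer seed through one
  generator stream; a fixed seed gives bit-identical output.

## Validation harness and problem sizes

The test suite validates the pipeline at three levels, with problem sizes
chosen to keep Monte Carlo error well below the effects being checked
while keeping a full run around ten seconds:

1. **Exact oracles.** Least squares against an explicit normal-equations
   solve ($10^{-8}$); the cluster sandwich against a brute-force
   loop-over-clusters summation ($10^{-10}$) and against an independent
   implementation from the `sandwich` package; measure constructors over
   their full input grids ($8^3$ meal-day combinations, all 4 activity
   levels, randomised vegetable batteries against $1-\max$).
2. **Distributional properties.** Within-pair correlations at 5 000 pairs
   per zygosity against the closed forms $h^2+c^2$ and $0.5h^2+c^2$;
   agreement of the regression $h^2$ with Falconer's $2(r_{MZ}-r_{DZ})$
   within joint Monte Carlo error; design symmetries (member-order
   invariance, antisymmetric ENVDIF columns) at machine precision.
3. **Recovery experiments.** `recovery_experiment()` at 200 replicates of
   1 000 pairs per zygosity for the ACE shares (mean error within 2 Monte
   Carlo SEs); ENVDIF unbiasedness against the projection formula at 200
   replicates of 500 pairs per zygosity; test size for a null covariate at
   1 000 replicates of 500 pairs per zygosity against the 95% binomial
   band around 0.05.

## Limitations

The estimator inherits the classical twin-design assumptions: equal
environments across zygosity, no gene-environment correlation or
interaction, additivity of the three components, and random sampling of
pairs. The DF regression treats variance shares as unconstrained
regression coefficients, so interval estimates can extend outside
$[0, 1]$. ENVDIF coefficients are projections, attenuated relative to
structural per-unit effects in mixed-zygosity samples (see above).
Percentile-scaled outcomes attenuate variance shares slightly. None of
the suite's synthetic checks can validate the equal-environments
assumption or covariate measurement quality in real data.
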