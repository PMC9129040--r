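---
title: "Modelling snakebite incidence as a zoonotic contact process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling snakebite incidence as a zoonotic contact process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakespill)
```

## The model

Snakebite can be treated as a zoonotic spillover process: venom plays the
role of the transmitted agent, venomous snakes are the reservoir (with 100%
"prevalence"), and a bite is the contact event. On a landscape divided into
square cells, the number of people bitten in a cell over one year is

$$H_b = H_s \, P(t, t+1), \qquad P(t,t+1) = 1 - e^{-\beta S},$$

the discrete-time (annual) form of the susceptible–bitten mass-action
dynamics $dH_b/dt = \beta H_s S$, where $H_s$ is the susceptible human
population of the cell, $S$ the snake abundance and $\beta$ the human–snake
contact rate. `snakespill` implements this form together with five
alternative density-dependent contact structures (power, two refuge
formulations, and two asymptotic formulations), all exposed by
`discretise()` and `contact_probability()`:

| name | annual probability |
|---|---|
| `mass_action` | $1-e^{-\beta S}$ |
| `power` | $1-e^{-\beta H^{p-1} S^{q}}$ |
| `refuge_on_S` | $1-e^{-\beta (S/H)(1 - H/(q_h S_{raw}))_+}$ |
| `refuge_on_H` | $1-e^{-\beta S (1 - S_{raw}/(q_s H))_+}$ |
| `separate_asymptotic` | $1-e^{-\beta S/(1-\varepsilon+\varepsilon X)}$, $X \in \{S_{raw}, H\}$ |
| `asymptotic` | $1-e^{-\beta S c/(c+X)}$, $X \in \{S_{raw}, H\}$ |

Two typographical ambiguities in the printed sources of the asymptotic rows
had to be resolved. We adopted the reading under which the
separate-asymptotic form reduces *exactly* to mass action at
$\varepsilon = 0$ (a property the sources state explicitly, and which the
test suite asserts over $10^5$ random states), and under which $c$ is the
number of snakes or humans at which half the asymptotic contacts occur.
Both "on $S$" and "on $H$" branches are implemented as named variants
(`asymptote_on`), but these forms are excluded from the default selection
set: they could not be estimated reliably in the reference analysis either.

Two arguments, `S` and `S_raw`, feed each form. The linear contact term
takes the *species-weighted* abundance (below), while the refuge and
saturation brackets compare snake numbers with human numbers and therefore
take the *total unweighted* abundance. Folding the species weights (of
order $10^{-5}$) into the bracket would make every refuge term vanish
numerically and reduce all forms to mass action — an artefact, not a model
property.

### Species decomposition and the human-impact adjustment

The contact rate is decomposed per snake species $s$:

$$S_t = \sum_s B_s \, A_s \, S_s \quad (\text{snakebite stage}), \qquad
  S_t = \sum_s B_s \, A_s \, E_s \, S_s \quad (\text{envenoming-as-contact}),$$

with $B_s \ge 0$ a per-species contact-rate scale, $A_s \in (0,1]$ an
aggressiveness index and $E_s \in (0,1]$ an envenoming-severity index
(`species_traits()`, `effective_abundance()`). The indices themselves are
not published; the package ships a clearly-labelled synthetic placeholder
table (`inst/extdata/species_traits_synthetic.csv`) and every test uses
synthetic traits.

Humans depress snake abundance. That is absorbed into a strictly positive
multiplier of effective abundance, stratified by land-cover class $l$
(5 classes: agriculture, degraded forest, forest, tea, urban):

$$S' = \beta(H, l)\, S_t, \qquad
  \beta(H,l) = \exp\{b_{0,l} + b_{1,l} \ln(H+1)^2\}$$

for the selected log-squared form; linear, quadratic and
linear-plus-quadratic alternatives are available
(`abundance_adjustment()`). Two numerical choices: the multiplier applies
in exactly one place — to effective abundance before the contact form, the
same adjusted abundances the envenoming stage consumes — and the logarithm
uses $\ln(H+1)$ so that empty cells are finite and evaluate exactly to
$e^{b_0}$ (the sources never state an offset; zero-population cells would
otherwise produce $-\infty$).

### Envenoming stage

Envenomings are the subset of bites that deliver clinically significant
venom. Conditional on bites,

$$\mathrm{logit}(P_{env}) = B_{LC}(l) + \sum_s B_s E_s S'_s, \qquad
  H_{env} = H_b \, P_{env},$$

with unconstrained species effects $B_s$ and an optional land-cover random
intercept $B_{LC}$ (`envenoming_model()`, `envenoming_probability()`). The
two stages are fitted sequentially — the envenoming model conditions on the
snakebite stage's posterior-mean expected bites — mirroring the selected
workflow of the reference analysis rather than a joint fit.

### Observation model and spatial effects

Counts are Poisson, $y \sim \mathrm{Pois}(H_b)$, or negative binomial
parameterised by $P_N = r/(r + H_b)$ with dispersion $r \sim U(0, 50)$ (the
only prior the reference analysis prints); $r$ may be global or
per-land-cover-class. The spatial variant adds a log-linear random
intercept, $\log H_b \mathrel{+}= \rho_i$, where $\rho$ is an intrinsic
conditional autoregressive (CAR) field on the queen (8-cell)
neighbourhood: each $\rho_i$ is normal about the mean of its neighbours,
with kernel $-(\tau/2)\sum_{i\sim j}(\rho_i-\rho_j)^2$ (`car_adjacency()`,
`car_logdensity()`). Whether the original field was intrinsic or proper is
not stated; we chose the intrinsic variant with sum-to-zero centring, which
matches "proportional to the average of its immediate neighbours" and
yields a proper posterior through the likelihood.

## Estimation

`build_model()` wires a landscape and a specification into a log-posterior
over the free parameters and `sample_posterior()` draws from it with a
bespoke adaptive Metropolis-within-Gibbs sampler: blocked proposals
(species scales | land-cover coefficients | shape parameters | dispersion)
with Haario-style covariance adaptation and Robbins–Monro scale tuning
toward 23–44% acceptance, multiplicative (log-scale) random walks for
positive parameters, adaptation strictly confined to burn-in, and the
per-iteration deviance recorded for DIC. Three structural devices matter:

* **Covariate centring.** Within each class the intercept and slope of the
  adjustment are nearly collinear because $\ln(H+1)^2$ has a large mean.
  The sampler works in per-class centred coordinates
  $b_{0,l}^c = b_{0,l} + b_{1,l}\overline{x}_l$ (a linear, unit-Jacobian
  reparameterisation); stored samples and priors are in the natural
  coordinates.
* **The gauge move and its anchor.** Multiplying every $B_s$ by $k$ while
  subtracting $\log k$ from every $b_{0,l}$ leaves all predictions
  unchanged — an exact ridge the sources acknowledge. The sampler travels
  it with a dedicated one-dimensional move, and the prior set pins it with
  a tight normal anchor on $\mathrm{mean}_l\, b_{0,l}$ (sd 0.1 by
  default). The anchor must be tight: along the ridge, any prior that is
  flat in $B_s$ near zero exerts a systematic volume pull of order
  $n_{species}\sigma_{anchor}^2$ on $\log B_s$. Reported $B_s$ are thus
  defined in the gauge where the intercepts average zero, and the synthetic
  truth uses the same convention.
* **CAR updates.** The field is updated by chequerboard-vectorised
  single-site Metropolis (cells of one colour are conditionally
  independent given the rest), $\tau$ by its conjugate gamma draw, and the
  field recentred to sum to zero each sweep with the shift absorbed into
  the adjustment intercepts — an exactly likelihood-preserving projection
  onto the constrained parameterisation.

Priors beyond the printed $r \sim U(0,50)$ are package defaults, flagged as
such and overridable through `prior_set()`: half-normal(5) for $B_s$,
normal(0, 10) for land-cover coefficients and envenoming effects,
gamma(1, 0.01) for $\tau$, normal(1, 1) for power exponents. The refuge
fractions $q_h, q_s$ — fraction-like order-one quantities by definition —
get a log-normal(0, 1.5); a prior spanning many orders of magnitude would
park essentially all mass where the refuge bracket is numerically inert
and the refuge models collapse onto mass action. The half-saturation
constant $c$, by contrast, is a population scale of genuinely unknown
magnitude and keeps a wide log-normal(0, 5). `warm_start()` converts a
converged non-spatial fit into normal priors for $b_0$, $b_1$ and $B_s$
only, for the spatial refit. Default burn-in is half the chain and
retained draws are thinned to at most 5,000 per chain.

One DIC detail: the plug-in deviance is evaluated at the component-wise
posterior *median*. With a free refuge constant the posterior is a curved
ridge — small $q_s$ pairs with compensated intercepts and the $q_s$
marginal is strongly right-skewed — and the component-wise mean falls off
the ridge, which can push the plug-in deviance above every sampled value
and make $p_D$ negative. The medians stay on the ridge; for the
near-Gaussian posteriors of well-identified models the two coincide.

## Model selection and diagnostics

Selection follows four criteria: convergence (Gelman–Rubin
$\hat R < 1.05$, the strict reference threshold), reproduction of the
spatial pattern (Pearson correlation with a Clifford–Richardson modified
t-test whose effective degrees of freedom shrink with the product of the
two fields' spatial autocorrelations, summed over displacement lags up to
half the grid extent), DIC ($p_D = \bar D - D(\bar\theta)$,
$DIC = \bar D + p_D$), and distributional adequacy via quantile–quantile
comparison. `select_model()` ranks converged fits by DIC but passes over a
DIC-best model whose maximum quantile gap exceeds 20% of the reference
interquartile range — the numeric counterpart of the visual judgement that
led the reference analysis to prefer mass action over a DIC-better refuge
model. The threshold is configurable; some rule is needed for automation.

`gelman_rubin()` uses the variant $\hat R = \sqrt{(W + V_m)/W}$ with $W$
the mean within-chain variance and $V_m$ the variance of chain means: it
equals the classic pooled-variance PSRF up to $O(1/n)$, is exactly 1 for
duplicated chains and never falls below 1. `geweke()` compares 10%/50%
window means with spectral standard errors from an AIC-selected
autoregressive fit (unbiased for white noise, robust for positively
autocorrelated chains); a constant chain returns 0 with a warning.

## The synthetic landscape generator

Real inputs for this kind of analysis (survey-derived incidence surfaces,
point-process abundance maps, census rasters) are external and cannot be
redistributed, so validation rests on synthetic landscapes with known
truth (`scenario_config()`, `generate_landscape()`, `simulate_counts()`).
The generator emulates the statistical structure the analysis assumes:

* per-species abundance: exponentiated Gaussian random fields (circulant
  embedding, exponential covariance, correlation length 4 cells) with
  log-normal marginals around 400 snakes per 25 km² cell (~16/km², a
  plausible density for common venomous species);
* human density: a log-normal field (median 2,000 people per cell,
  log-sd 1, correlation length 6) with a few multiplicative hotspots
  standing in for towns;
* land cover: blocky patches (5-cell blocks drawn by class proportions
  0.35/0.2/0.25/0.1/0.1), covering all five classes;
* counts: drawn from the model's own mass-action + adjustment forward pass
  (default per-species scales of order $10^{-5}$, giving bite incidences
  around 1%/year) with Poisson or negative binomial noise, optional
  multiplicative CAR heterogeneity $e^{\rho}$, and envenomings as a
  *binomial thinning* of bites — enforcing the subset relation
  envenomings ≤ bites ≤ population cellwise, which the two-stage model
  implies but never states distributionally. Count draws are capped at the
  cell population; at these scales the cap is essentially never active.

One master seed drives derived per-layer streams, so adding a species does
not perturb the human field. What the generator does **not** emulate: the
real geography of any country, sampling artefacts of survey-derived
incidence surfaces, temporal (seasonal) structure, or correlation between
species' ranges and land cover. Passing recovery tests therefore shows the
estimation machinery is correct and calibrated under the model's own
assumptions — not that the model is adequate for any particular real
data set.

## Problem sizes and acceptance experiments

The shipped tests exercise, among others: parameter recovery on twenty
seeded 10×10 two-species Poisson landscapes (two land-cover classes,
two chains of 25,000 iterations each, half burn-in), requiring 95%
credible-interval coverage of the true $B_s$ and $b_{1,l}$ in at least 90%
of replicates and mean relative bias of posterior medians under 15%; DIC
ranking of mass action above refuge-on-$H$ on mass-action data in at least
80% of ten seeds — run on a human-sparse scenario (median 300 people per
cell) where adjusted snake and human numbers are commensurate, because a
model-discrimination experiment is only informative where the candidate
models actually differ; Geweke |z| < 2 for at least 95% of 2,000 white-noise
chains; and Clifford-corrected type-I error within [2%, 8%] over 500
autocorrelated null pairs. `scripts/acceptance.R` re-runs scaled versions
of the same experiments from scratch. These sizes were chosen so the whole
validation remains a desk-scale computation; all thresholds come from the
design, not from observed outcomes.

## Known limitations

* The intrinsic-vs-proper CAR choice and all unprinted priors mean
  posteriors from the original study cannot be replicated exactly even
  with the original rasters; recovery tests quantify behaviour under the
  package's own defaults instead.
* $B_s$ is only identified up to the gauge convention; comparisons of
  $B_s$ across fits are meaningful only under the same anchor.
* The refuge and asymptotic discrete forms inherit the documented
  interpretation of typographically ambiguous sources; both asymptotic
  branches are provided but excluded from default selection.
* The intrinsic CAR intercept is subject to spatial confounding: when
  per-cell counts are large, the field can absorb covariate structure,
  deflating the precision `tau` and destabilising the main effects. The
  two-step workflow — fitting the non-spatial model first and converting
  its posterior into [warm-start priors](#estimation) for $b_0$, $b_1$ and
  $B_s$ — is the package's (and the reference workflow's) mitigation, and
  the spatial variant should not be fitted cold.
* Bilinear resampling of incidence rates does not conserve case totals
  (by design; counts aggregate by summation). Whether incidence should
  instead be re-derived from aggregated counts is left to the user — both
  routes are supported, and the pipeline default resamples rates.
* No reprojection between coordinate reference systems: inputs are assumed
  planar and on commensurable grids. On-disk storage uses a plain-text CSV
  dialect with a JSON sidecar rather than GeoTIFF.

## A minimal worked example

```{r, eval = FALSE}
fx <- make_fixture("minimal", seed = 1)
m <- build_model(fx$landscape, fx$truth$spec, prior_set())
s <- sample_posterior(m, n_iter = 25000, n_chains = 2, seed = 1)
summary(s)
compute_dic(s, m)
```
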