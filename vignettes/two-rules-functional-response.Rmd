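---
title: "Two energetic rules for predator functional responses: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two energetic rules for predator functional responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frpred)
```

## The model

A Holling type II functional response describes a predator's per-capita
feeding rate as a saturating function of prey density $N$:

$$f(N) = \frac{aN}{1 + ahN},$$

with two parameters: the space clearance rate $a$ (area effectively searched
per predator per day; the slope at the origin) and the handling time $h$
(days per prey; $1/h$ is the maximum feeding rate). `frpred` predicts both
parameters from two energetic constraints rather than from proximate
mechanisms such as movement speeds or detection distances:

1. **Demand at scarcity.** Over the long term a predator must meet its
   energetic demand at the low prey densities it routinely experiences.
   At low density the response is effectively linear ($f_{low} = aN_{low}$),
   so
   $$D = a\,N_{low}\,E\,M_N,$$
   where $D$ is demand (kJ/day), $E$ prey energy density (kJ/g wet mass)
   and $M_N$ prey mass (g).
2. **Saturation at abundance.** The feeding rate should approach its
   maximum near the highest prey densities the predator experiences;
   saturating earlier would forfeit intake exactly when prey are plentiful,
   while maintaining capacity to saturate later is costly. With the degree
   of saturation defined as $f(N)\,h \in [0,1)$,
   $$I_S = f(N_{high})\,h.$$

Solving the two constraints gives the package's core predictions
(`predict_space_clearance()`, `predict_handling_time()`):

$$a = \frac{D}{N_{low} E M_N}, \qquad
  h = \frac{I_S\,N_{low}\,E\,M_N}{D\,N_{high}\,(1-I_S)}.$$

Three corollaries follow algebraically and are exposed directly:
the half-saturation density $1/(ah) = (1-I_S)N_{high}/I_S$
(`half_saturation_predicted()`); the inverse relationship
$\ln a = \ln[I_S/((1-I_S)N_{high})] - \ln h$ among predators whose prey
reach similar high densities (`predicted_a_from_h()`); and, combining with
standard mass-scaling laws, the allometries of both parameters (the
allometry module, below).

### Assumptions worth keeping in view

* The linear approximation $f_{low} = aN_{low}$ is used where rule 1 is
  imposed. It is adequate when $ahN_{low} \ll 1$; every prediction row
  carries this product as a diagnostic (`ah_Nlow` column,
  `low_density_linearity()`). In the default synthetic study its median is
  about 0.03.
* $E$ and $I_S$ are treated as mass-independent constants. Assimilation
  losses can be folded in through the optional `assimilation` multiplier on
  $E$ (default 1).
* $I_S$ has a second reading as the steady-state fraction of predators busy
  handling prey. The package implements the defining identity
  $I_S = f\,h$ only; the steady-state queueing argument behind the second
  reading is not re-derived here.
* The theory is for a single predator-prey pair with a type II response; no
  type III responses, prey depletion within experiments, or multi-prey
  dynamics.

## Units

Canonical units are fixed package-wide: masses in g wet weight, densities
in individuals per aerial m², demand in kJ/day, energy density in kJ/g,
$a$ in m²/day, $h$ in days. Experiments in volumetric arenas must be
converted by the caller — `clearance_volume_to_area()` divides a m³/day
rate by an explicit depth; no per-study depth is guessed.

## Estimating the context from mass-scaling laws

For compilation-scale prediction, the context quantities are estimated from
two classic scaling laws fitted per taxon group on the log10 scale
(`fit_loglog()`):

* density on mass (Damuth's law) for prey groups: prokaryotes, protists,
  invertebrates, ectotherm vertebrates, mammals, birds;
* basal metabolic rate on mass (Kleiber's law) for predator groups: the
  same set minus prokaryotes.

The model is $\log_{10} y \sim N(\alpha + \beta \log_{10} x, \sigma)$ with
flat priors on $\alpha, \beta$ and a half-Student-t(3, 0, 2.5) prior on
$\sigma$, sampled by MCMC (JAGS) with 4 chains × 1000 post-warmup draws
after 1000 warmup iterations, initialised at the least-squares solution.
Group labels outside the sets above raise an error — no fallback law is
ever substituted.

$N_{low}$ and $N_{high}$ are the 0.10 and 0.90 quantiles of the posterior
predictive distribution of the prey group's density law at the prey mass —
the spread of the density data is read as the boom-bust range of densities
a predator experiences, not as noise to be averaged away. $D$ is the
predictive median of the metabolic law at the predator mass. Defaults
$E = 5.6$ kJ/g wet weight and $I_S = 0.9$; all of $I_S$, the quantiles and
$E$ are configurable, and `sweep_predictions()` re-runs the comparison over
grids of them (in the default synthetic study the comparison statistics are
essentially unchanged across $I_S \in [0.8, 0.95]$ and quantile pairs from
25/75 to 5/95).

**Numerical choice: predictive quantiles.** The posterior predictive
distribution is a mixture of normals over posterior draws. Rather than
pooling one simulated predictive draw per posterior draw, the quantile is
computed deterministically as the root of the mixture CDF (bracketed by the
extreme per-draw quantiles; `uniroot` at tolerance 1e-10). This removes
Monte Carlo error, is exactly monotone in $q$, and reduces exactly to the
lognormal quantile $10^{\alpha + \beta\log_{10}m + \sigma z_q}$ for a
single draw — which is what makes plug-in laws (`scaling_law()`) reproduce
closed-form evaluations bit-for-bit. Because $10^x$ is monotone, computing
the quantile on the log scale and back-transforming is exact, not an
approximation.

## Model II regression

Observed and predicted parameters both carry error, so comparisons use
model II regression on the log10 scale: reduced major axis
(`fit_rma()`; slope $\mathrm{sign}(r)\,s_y/s_x$) for observed-vs-predicted
parameter comparisons, and major axis (`fit_major_axis()`; first principal
axis of the covariance matrix) for the auxiliary tests. Confidence limits
follow the classical formulas: the Jolicoeur-Mosimann F-based interval for
MA (returned as unbounded when the confidence sector includes the vertical,
and as zero-width for exactly collinear data) and the correlation-based t
interval for RMA. Intercept intervals are propagated from the slope limits
through the centroid. The suite verifies the MA slope against an
eigendecomposition oracle at 1e-10 and checks 95% CI coverage over 500
simulated errors-in-both-variables datasets.

A caution encoded in the tests: MA is *not* equivariant under rescaling a
single axis (only under rescaling both axes together), which is the
standard reason to prefer RMA when the two variables are on different
scales. Comparisons here are log10-log10, where either is defensible.

Alongside each fit the package reports $R^2$ about the 1:1 line,
$1 - \sum(y-x)^2/\sum(y-\bar y)^2$: variance explained by taking the
prediction at face value. It can be negative when the identity line fits
worse than the mean.

## The replication pipeline

`apply_exclusion_filters()` retains experiments with living, non-egg prey,
handling times above $10^{-6}$ days (smaller fitted values flag poor type
II fits), and both masses present. A record failing several rules is
attributed to the first failing rule in that order (the order is a
documented tie-break; counts by any-rule are logged too, and filtering is
idempotent). `predict_all()` then joins the scaling laws, builds each
record's full energetic context, and emits predicted and observed $(a, h)$
side by side; the context travels with the row so that `demand_check()`
can audit any prediction. `predict_field_study()` is the scaling-free path:
system-specific $D$, $E$, $M_N$ and recorded density extremes evaluated
directly, with prey energy density optionally derived from percent
protein/fat composition at 16.74 and 33.47 kJ/g.

## The allometry module

Treating $E$ and $I_S$ as constants, power-law scalings propagate through
the predictions linearly in the exponents: with $D \propto M_P^{e_D}$ and
$N_{low}, N_{high} \propto M_N^{e_{low}}, M_N^{e_{high}}$,

$$a \propto M_P^{e_D} M_N^{-e_{low}-1}, \qquad
  h \propto M_N^{e_{low}+1-e_{high}} M_P^{-e_D}.$$

At the canonical empirical inputs $(e_{low}, e_{high}, e_D) =
(-0.94, -0.9, 0.87)$ this gives $a \propto M_P^{0.87} M_N^{-0.06}$ and
$h \propto M_N^{0.96} M_P^{-0.87}$; composing with the prey-on-predator
mass scaling $M_N \propto M_P^{0.79}$ gives $a \propto M_P^{0.8226}$. For
the prey-mass-specific handling time $h/M_N$ two composed values are
reported deliberately: the predator-mass part alone ($-0.87$, the usual
quotation, which drops the small residual $M_N^{-0.04}$) and the full
composition ($-0.87 - 0.04 \times 0.79 = -0.9016$). Exponents are kept at
full precision; rounding to two decimals is a separate display step.

## The synthetic-data generator

`generator_config()` defines a fully known generative world: log-uniform
predator masses over $10^{-6}$–$10^6$ g; prey mass from
$\log_{10} M_N = -2 + 0.79 \log_{10} M_P + N(0, 1.5)$; per-group density
and demand laws with slopes $-0.94$ and $0.87$ and group-specific
intercepts; true $N_{low}/N_{high}$ as the 10/90 lognormal density
quantiles at the prey mass; true $(a,h)$ from the two rules with
$E = 5.6$, $I_S = 0.9$; observed values equal to truth times
$10^{N(0,\sigma_{obs})}$ with $\sigma_{obs} = 0.5$ by default. Optional
fractions of egg-prey rows, sub-floor handling times and missing masses
exercise the filters.

Choices that deserve justification:

* **Density residual σ = 1.0 log10 units.** An order of magnitude of
  density spread at fixed mass, consistent with reading the scatter of
  density compilations as real boom-bust and among-species variation.
* **Prey-mass scatter 1.5 log10 units.** Predator-prey mass ratios at a
  given predator size vary over several orders of magnitude; this value
  makes the synthetic clearance rates and handling times span roughly 15
  and 10 orders of magnitude, matching the very wide spreads such
  compilations show. With much smaller scatter, handling times would
  collapse onto a narrow band (their predator-mass and prey-mass
  dependencies nearly cancel along the $M_N$–$M_P$ ridge).
* **One density law per group.** Within a group the generative model
  forces the $N_{low}$ and $N_{high}$ exponents to be equal (both equal
  the density slope); empirically distinct low/high exponents such as
  $-0.94$ vs $-0.9$ arise from pooling heterogeneous groups. The allometry
  module handles arbitrary distinct exponents; the generator defaults use
  $-0.94$ for both, which is the value that drives the $a$ allometry.

What the generator does *not* emulate: arena-geometry (2D vs 3D) unit
heterogeneity, taxonomic structure beyond group labels, non-independence of
density records from the same species, temperature effects, and the raw
feeding-trial fitting step that produces $(a,h)$ estimates in real
compilations. Passing the end-to-end tests therefore shows the inference
chain is correct and self-consistent under the stated statistical
structure — not that the theory is validated against nature.

## Validation strategy and problem sizes

The suite follows a dual-route pattern: every nontrivial computation is
checked against an independent oracle (root-finders and bisection for the
closed forms; eigendecomposition for MA; OLS limits and Monte Carlo
predictive samples for the Bayesian fits; exact bookkeeping for the
generator). The deterministic end-to-end identity — a noiseless cohort run
through the full pipeline returns predicted = observed exactly, all
comparison slopes 1 — is checked at n = 1000, the stochastic recovery study
at n = 2000 with $\sigma_{obs} = 0.3$ and 400 scaling observations per
group, the within-stratum inverse a-h check at n = 20000 (noiseless,
strata of 0.25 decades of $N_{high}$), and CI coverage over 500 replicate
fits of n = 50; these sizes give stable statistics while keeping the whole
suite in a few minutes.

One recovery-scale caveat is worth stating because it is a property of the
estimator, not a bug: with multiplicative observation noise on the observed
axis only, the RMA slope estimates $s_y/s_x = \sqrt{1 +
\sigma_{obs}^2/\mathrm{Var}(\log_{10}\text{truth})} > 1$. At n = 2000 and
$\sigma_{obs} = 0.3$ this bias (≈0.5–2%) exceeds the width of the 95% CI,
so the slope CI sits just above 1 even though the predictions are exactly
calibrated — the same mechanism that makes slope estimates differ
significantly from 1 on real compilations. The point estimates remain well
inside (0.7, 1.3) with correlations far above 0.5.

## Known limitations

* Exponent propagation is dimension-blind: no 2D vs 3D interaction
  geometry, so the module cannot produce dimension-specific allometries.
* The Bayesian fits pool all records within a group; repeated measures of
  the same species are treated as independent, as in the compilations the
  schema mirrors.
* Field-study mode performs no automatic circularity screening; records
  whose kill rates were derived from diet proportions must be flagged via
  the `diet_derived` column by the data curator.
* MA confidence intervals wrap through infinity for very weak signals and
  are then reported as unbounded rather than as disjoint sectors.
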