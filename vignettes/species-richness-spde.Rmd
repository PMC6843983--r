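---
title: "Modelling species richness on a lattice with an SPDE Matérn field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling species richness on a lattice with an SPDE Matérn field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richlattice)
```

## The model

The analysis unit is a 10 × 10 km lattice cell indexed by $i$, whose response
$O_i$ is the number of species (amphibians, reptiles, birds and mammals)
recorded in the cell. We assume

$$O_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \mathbf{x}_i^\top\boldsymbol\beta + u_i + v_i,$$

where $\mathbf{x}_i$ collects an intercept, indicator columns for
quantile-categorised covariates (slope, hillshade, elevation and the
distances to urban areas, roads and railways in quintiles; aspect in
quartiles; the first group is always the reference), indicators for an
8-level land-use classification (reference `other`, which pools urban,
beaches, sand, bare rock, burnt areas and water bodies), and optional
continuous temperature-variation covariates. Exponentiated coefficients are
relative risks: $\exp(\beta_k)$ is the multiplicative change in expected
richness for category $k$ against its reference.

Two random effects absorb what the covariates cannot. The *structured*
effect $u$ captures spatial clustering from unobserved, spatially smooth
confounders: it is a zero-mean Gaussian field with smoothness-1 Matérn
correlation $r(d) = (\kappa d)\,K_1(\kappa d)$, $\kappa = \sqrt8/\rho$, so
the range $\rho$ is the distance at which correlation has fallen to about
0.1. The *unstructured* effect $v_i \sim N(0, \sigma_v^2)$ captures
cell-specific heterogeneity. `excess_surface()` reports
$\exp(u_i + v_i)$, the multiplicative departure of each cell from its
covariate-predicted richness.

## The SPDE construction

Rather than a dense covariance, the field is built as a Gaussian Markov
random field: the Matérn field with $\nu = 1$ in two dimensions solves a
stochastic partial differential equation whose finite-element discretisation
yields the sparse precision

$$Q = \tau^2\big(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\big),$$

with $C$ the (lumped, hence diagonal) mass matrix and $G$ the stiffness
matrix of the mesh, and $\tau^2 = 1/(4\pi\kappa^2\sigma_u^2)$ fixing the
interior marginal variance at $\sigma_u^2$. Design choices:

* **Mesh.** The lattice itself is the mesh — nodes are cell centroids,
  squares split into two right triangles — so the projector from mesh nodes
  to cells is a simple selection. On this mesh the stiffness matrix reduces
  to the familiar five-point stencil, and $Q$ has a two-step neighbourhood.
* **Boundary.** The mesh is padded with two rings of ghost nodes; the field
  is reported only at real cells. Without padding the Neumann boundary of
  the SPDE inflates the variance at edge cells by up to ~50%; with two rings
  the interior-variance check stays within ±15% of nominal and the implied
  correlation matches the closed form within 0.05 out to $3\rho$
  (verified in the test suite on a 40 × 40 lattice).
* **Identifiability.** A constant shift can travel between the intercept and
  the field. Instead of a rank-one soft constraint in the precision (which
  would destroy sparsity), every posterior draw is recentred: the mean of
  $u$ over real cells is moved into the intercept. This is an exact
  reparameterisation of the likelihood, applied draw-wise.

## Priors

Penalised-complexity priors shrink towards the simpler base model (no field,
no heterogeneity). They are parameterised by tail statements: by default
$P(\rho < \text{domain diameter}/5) = 0.5$ and $P(\sigma_u > 1) = 0.01$ for
the field, and $P(\sigma_v > 1) = 0.01$ for the heterogeneity sd — on a
log-count scale a sd of 1 already means ±170% cell-level swings, so these
are weakly informative upper guards. Coefficients get independent
$N(0, 5^2)$ priors. All are configurable through `pc_prior_spec()` and
`model_spec()`; the source analysis did not publish its hyperparameters, so
these defaults are this package's own documented choice.

## Inference

The default path (`method = "laplace"`) mirrors the nested-approximation
strategy used with latent Gaussian models: for hyperparameters
$\theta = (\log\rho, \log\sigma_u, \log\sigma_v)$ the latent vector
$(\boldsymbol\beta, u, v)$ is Gaussian a priori and log-concave a
posteriori, so its conditional mode is found by a sparse Newton solver and
its conditional posterior replaced by the Gaussian at the mode. The
resulting Laplace approximation to $p(\theta \mid y)$ is maximised
(Nelder–Mead on the log scale); hyperparameter uncertainty is propagated by
sampling $\theta$ from the Gaussian approximation at the optimum
(`hyper_draws` samples, finite-difference Hessian) and drawing the latent
field from its conditional Gaussian at each sampled $\theta$. Summaries are
then computed draw-wise — in particular relative risks are
$\mathrm{mean}(\exp(\beta))$, not $\exp(\mathrm{mean}(\beta))$.

An exact MCMC (`method = "mcmc"`) is provided as a cross-check. Each
iteration combines (a) a preconditioned Metropolis-adjusted Langevin step on
the latent vector, (b) an independence refresh from the conditional Gaussian
approximation, and (c) a joint $(\theta, z)$ move that proposes $\theta$ by
random walk and the latent vector from the Gaussian approximation at the
proposed $\theta$ — the joint accept ratio sidesteps the notoriously slow
field/variance coupling. Split-chain scale reduction above 1.05 on any
coefficient raises an error (the gate covers the coefficients whose relative
risks are reported; hyperparameter $\widehat R$ values are returned in the
diagnostics, where the heterogeneity sd is the slowest direction). The
Laplace path is the default because the source analysis itself used an
integrated nested Laplace approximation and because it is deterministic
given a seed; the test suite checks that both paths agree on the
coefficients within Monte-Carlo error.

With both random-effect sds pinned near zero the fit collapses to a
(barely) ridge-penalised Poisson GLM; the suite verifies agreement with
`glm.fit` relative risks within 1%.

## Temperature statistics

The temperature covariate of interest is the *year-over-year variation*: for
every calendar day present in two consecutive years, the difference between
the day's value and the same calendar day one year earlier. February 29 has
no counterpart and is dropped; missing observations are skipped, not
imputed. Variations are averaged over the whole period and stratified by
meteorological season (Mar–May spring, Jun–Aug summer, Sep–Nov autumn,
Dec–Feb winter — month-based strata, since no calendar convention was stated
in the source). Both the per-season means and the annual mean are exposed;
either can feed the regression as continuous covariates.

The multi-year trend is estimated from the model
*temperature = station intercept + annual harmonic + linear trend + noise*,
with the station intercepts a REML random effect (lme4). Under flat priors
the REML fixed-effect distribution is the approximate posterior, so the
trend is reported with mean, sd and 2.5/97.5% Gaussian quantiles, per year
and per 5 years. One harmonic pair is the default; with harmonics and
station effects disabled the estimate reduces exactly to the least-squares
slope. The published "annualised percentage" increases have no stated
baseline and are deliberately not reproduced; trends are reported in °C
only.

Interpolation of station-level variation summaries onto cell centroids uses
Gaussian-process (kriging) prediction with the same smoothness-1 Matérn
covariance plus a nugget, with a generalised-least-squares constant mean.
Hyperparameters are user-supplied or, with `estimate = TRUE`, profiled by
maximum likelihood. For small networks the implementation equals the dense
textbook conditional mean to $10^{-8}$ (tested).

## The synthetic-data generator

No species or station data are deposited with the source analysis, so the
generator reproduces the assumed data-generating process exactly, making
every stage testable by parameter recovery:

* **Stations** (default 190, daily 2007–2011): mean + annual harmonic
  (amplitude 8 °C, peaking late July) + linear trend (defaults 0.159 and
  0.332 °C per 5 years for maximum and minimum temperature — the published
  magnitudes) + a spatially correlated station baseline (Matérn, range
  50 km, sd 1.5 °C) + independent daily noise (sd 2 °C, the residual
  day-to-day variability left after station and seasonal structure).
  Locations are uniform over the lattice bounding box.
* **Lattice covariates**: half-normal slope, uniform aspect/hillshade on
  [0, 360), gamma elevation, lognormal distances, a configurable 8-level
  land-use categorical. Only the quantile boundaries matter downstream, so
  the families are chosen for realistic shapes, not calibrated to Catalonia.
* **Counts**: the exact regression model above, with defaults
  $\sigma_u = 0.5$, range 30 km, $\sigma_v = 0.2$, intercept $\log 150$.
  The realised field, heterogeneity, $\mu_i$ and coefficients are returned
  as a `synthetic_truth` object.

One master seed is split deterministically into per-stage substreams so
stages can be regenerated independently; identical configurations are
byte-identical.

What the generator does *not* emulate: the real geography and station
network of Catalonia, sampling-effort differences between cells (no offset
is generated, matching the raw-count model; an offset column is supported
but off by default), multi-year dynamics of counts, and space–time
interaction in temperatures. Passing recovery tests therefore demonstrates
correctness of the estimators under the model's own assumptions, not
robustness to real-data violations of them.

## Numerical choices and scaled-down study sizes

* Newton iterations stop when the objective changes by less than
  $10^{-9}(1 + |f|)$; the linear predictor is capped at 35 to keep the
  line search finite far from the mode.
* Quantile categorisation uses type-7 empirical quantiles with right-closed
  intervals, so boundary ties fall into the lower category; fewer than $k$
  distinct cut points is a degenerate-input error, not a silent merge.
* Slope and aspect are treated as degrees throughout; published
  descriptions of such terrain layers sometimes quote percent slopes or
  other units, so the unit convention is fixed here rather than inferred.
* Recovery studies in the tests use 20 × 20 lattices for headline effects,
  10 × 10 for the 30-replicate interval-calibration study, and 40-station
  networks for trend recovery; these sizes give each check useful power
  while keeping the whole suite quick to run routinely.

## Limitations

Counts are single-period totals; no temporal evolution, zero-inflation or
multi-taxon structure is modelled. The mesh is the lattice itself — for
strongly sub-cell ranges ($\rho \lesssim 2$ cells) the discretised
correlation is too coarse and the range becomes weakly identified. The
Laplace path underestimates skewness in the hyperparameter posteriors;
where that matters, run the MCMC path with generous iterations.
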