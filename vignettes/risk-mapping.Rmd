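---
title: "Small-area risk mapping with sirmap: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area risk mapping with sirmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirmap)
```

## The problem

Cancer registries geocode incident cases to very small administrative
areas — in Canada, census dissemination areas (DAs) of roughly 400–700
people.  At that scale the raw standardized incidence ratio (SIR)
$\hat\theta_i = Y_i / E_i$ is wildly unstable: a single case can move an
area between the lowest and highest map classes.  `sirmap` implements
the standard small-area disease-mapping pipeline that deals with this:

1. **Indirect standardization**: expected counts $E_i = P_i'\psi$ from
   each area's age–sex(-income) stratified population $P_i$ and a
   reference rate vector $\psi$, SIRs with exact Poisson intervals.
2. **Spatial screening**: global Moran's $I$ on the SIR surface, with a
   Poisson parametric bootstrap for inference and Bonferroni control
   across the family of outcomes screened.
3. **Hierarchical smoothing**: the Besag–York–Mollié (BYM) model by
   MCMC, giving smoothed SIRs, 95% credible intervals, exceedance
   probabilities $P(\theta_i > 1 \mid Y)$ and the spatial fraction of
   the random-effect variation.
4. **Scan corroboration**: a circular Kulldorff-style Poisson spatial
   scan with Monte-Carlo inference for the most likely cluster.
5. **Mapping**: a seven-class diverging classification centred on
   SIR = 1, with significance/exceedance flags standing in for the
   cross-hatch overlays of printed maps.

Because registry microdata and census stratum counts cannot be
redistributed, the package ships a **synthetic study-region generator**
that reproduces the statistical structure the pipeline assumes, so
every stage is testable end to end without any external data.

## The BYM model

For modelled areas (those with $E_i > 0$):

$$Y_i \sim \mathrm{Poisson}(E_i \theta_i), \qquad
  \log \theta_i = \alpha + u_i + v_i,$$

with $v_i \sim N(0, \sigma_v^2)$ i.i.d., a flat prior on $\alpha$, and
the intrinsic conditional autoregressive (ICAR) prior on
$u = (u_1,\dots,u_n)$,

$$p(u \mid \sigma_u^2) \propto
  \exp\!\Big(-\tfrac{1}{2\sigma_u^2}
  \sum_{i \sim j} (u_i - u_j)^2\Big),$$

summing over first-order contiguity pairs, together with the
sum-to-zero constraint that makes the improper prior identifiable.
Both precisions $1/\sigma_u^2, 1/\sigma_v^2$ get Gamma(0.5, 0.0005)
hyperpriors — the conventional WinBUGS-era disease-mapping default —
and both are configurable through `mcmc_config()`.

### Sampler

`fit_bym()` runs compiled single-site random-walk Metropolis sweeps
for $u_i$ and $v_i$, a Metropolis step for $\alpha$, and conjugate
Gamma draws for both precisions.  Numerical choices:

* **Re-centring.** After each sweep the mean of $u$ over non-island
  areas is subtracted from $u$ and added to $\alpha$.  For a connected
  graph this moves along an exactly flat direction of the posterior
  (likelihood and ICAR density are both invariant), so it costs
  nothing and pins the identifiable representative.  Island areas have
  $u_i$ fixed at 0 and their risk carried entirely by $v_i$; their
  $v_i$ absorbs the compensating shift so their likelihood term is
  untouched (a negligible perturbation of the proper $v$ prior, exact
  when there are no islands).
* **ICAR rank.** The Gamma update for $1/\sigma_u^2$ uses shape
  $a_u + (n_{\text{free}} - c)/2$ where $c$ is the number of connected
  components of the non-island subgraph — the rank of the intrinsic
  precision matrix.
* **Adaptation.** Proposal scales adapt per site toward 44%
  acceptance in batches of 100 sweeps during burn-in only, with
  diminishing steps $\min(0.1, 1/\sqrt{b})$; they are frozen afterwards
  so the saved draws come from a fixed-kernel chain.
* **Starting points.** Chains start over-dispersed: the intercept at
  $\log(\sum Y / \sum E)$ plus noise scaled by `init_dispersion`,
  random effects and precisions likewise jittered, so the
  Gelman–Rubin diagnostic is meaningful.

Two protocols are pre-wired: the `"desk"` default (2 chains, 5,000
burn-in, 20,000 iterations, thin 10) sized for simulation studies, and
`"replica"` (3 chains, 100,000 burn-in, 1,000,000 iterations, thin 200
— 15,000 saved draws over 3,000,000 post-burn-in iterations), the
heavyweight protocol used historically with registry data.  A
convergence gate attaches a warning to pipeline outputs when any
monitored $\hat R \ge 1.1$; the threshold is a package choice, since
visual chain inspection does not automate.

### Posterior summaries

`summarize_posterior()` reports the posterior mean SIR, the empirical
2.5%/97.5% quantiles and the exceedance probability
$P(\theta_i > 1 \mid Y)$ as the fraction of pooled draws above 1.
`spatial_fraction()` computes, per draw, the share of random-effect
variation that is spatial,
$\mathrm{Var}_{\text{emp}}(u) / (\mathrm{Var}_{\text{emp}}(u) +
\mathrm{Var}_{\text{emp}}(v))$, using empirical across-area variances;
a standard-deviation-ratio variant is available via `method = "sd"`
because the literature is not unanimous about which ratio "fraction
spatial" denotes.  The variance ratio is the default here.

## Moran screening

`morans_i()` computes
$I = (n/S_0) \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$ over areas with
defined SIRs; `parametric_bootstrap_p()` draws replicate counts
$Y^*_i \sim \mathrm{Poisson}(E_i)$ under the constant-risk null and
reports the one-tailed Monte-Carlo p-value
$(1 + \#\{I^* \ge I_{\text{obs}}\})/(B+1)$.  This null accounts for
population density automatically: small areas produce noisy SIRs in
the replicates exactly as they do in the data, which the asymptotic
normal test cannot do.  Design choices:

* The test is one-tailed for *positive* autocorrelation only, and the
  Bonferroni screen (`bonferroni_screen()`) additionally requires
  $I > 0$: with 24 outcomes at family-wise 0.05 the per-test threshold
  is $0.05/24 \approx 0.002$.
* The add-one Monte-Carlo convention guarantees $p \in (0, 1]$ with
  minimum $1/(B+1)$.
* Replicates with zero variance (possible when expected counts are
  tiny) are recorded as non-exceeding rather than discarded, keeping
  the p-value valid.
* Moran's I uses **row-standardized** weights by default while the
  ICAR prior uses binary weights — the conventional pairing; binary
  Moran weights are available through `binary_weights()`.

## Contiguity

`build_adjacency()` derives first-order neighbours from the polygon
layer: **queen** contiguity (any shared boundary point) is the
default, the common choice for irregular administrative polygons;
rook (shared boundary of positive length) is a flag.  Contacts are
detected by segment-distance tests with a `1e-8` snapping tolerance,
so tessellations produced by floating-point clipping and exact unit
grids both resolve correctly.  Islands are flagged, never dropped:
they are masked from the Moran numerator and carried by the
unstructured effect in the BYM model.

## The synthetic generator

`simulate_study()` draws, under one master seed with per-stage derived
sub-seeds:

* **Geometry** — Voronoi cells of uniformly random points clipped to
  the unit square (`generate_geometry()`), giving irregular,
  contiguity-rich areas resembling DAs rather than a grid.
* **Population** — area totals uniform on 400–700 (inclusive), split
  over age × sex strata by one multinomial draw with a fixed
  documented pyramid (0–14: 0.19, 15–44: 0.42, 45–64: 0.26, 65+: 0.13,
  sexes even).  The pyramid is a deliberate constant, not data-derived:
  stratum-level source pyramids are not redistributable, and any
  plausible fixed pyramid serves, provided expected counts are
  reproducible.
* **Income** — a continuous area income with a one-step
  moving-average spatial correlation over the adjacency graph, split
  into five rank-based quintiles (near-equal groups, remainder to the
  lower quintiles, ties broken by area ID).
* **Risk surface** — $u$ sampled from the ICAR distribution by
  eigen-decomposition of the graph Laplacian with the null direction
  removed, re-centred and rescaled so its *empirical* standard
  deviation equals `sigma_u` exactly (the intrinsic prior is improper,
  so the generator must fix a scale convention; this one makes the
  generator's spatial fraction calibrate to
  $\sigma_u^2/(\sigma_u^2+\sigma_v^2)$ by construction); $v_i$
  i.i.d. $N(0, \sigma_v^2)$.  With the defaults
  $\sigma_u = 0.3, \sigma_v = 0.1$ the target spatial fraction is 0.9.
* **Clusters** — an optional planted cluster multiplies the risk of
  all areas within a graph radius of a seed area.  The multiplier is
  carried inside $v$ so that $\theta = \exp(\alpha + u + v)$ holds
  exactly for every area, keeping the truth table self-consistent.
* **Cases** — $Y_{is} \sim \mathrm{Poisson}(P_{is}\,\psi_s\,\theta_i)$
  per stratum.

What the generator does **not** emulate: real census pyramids and
their spatial variation, postal-code geocoding error, income
suppression, non-Poisson overdispersion within strata, and boundary
effects of a real coastline.  Passing tests therefore demonstrate
that the pipeline's statistics behave as designed under the model's
own assumptions — not that any particular real-world surface would be
detected.

## Standardization details

* Exact (gamma-quantile) Poisson intervals,
  $[\,q_{\Gamma}(a/2; Y)/E,\; q_{\Gamma}(1-a/2; Y+1)/E\,]$, with lower
  limit 0 at $Y = 0$ — counts at DA scale are far too small for normal
  approximations.
* Internal standardization (rates re-estimated from the pooled study)
  satisfies $\sum_i E_i = \sum_i Y_i$ identically, which the tests
  verify to $10^{-9}$.
* Areas with $E = 0$ and $Y = 0$ (unpopulated) are excluded from the
  spatial stages but retained, flagged, in every output table and map.
  $E = 0$ with $Y > 0$ is rejected as impossible under the model.
* `aggregate_sir(..., reference = "complement")` rescales the zone's
  expectation by the complement's own $Y/E$, giving cluster SIRs
  "relative to the remainder of the study region".

## Scan statistic

Circular windows only: zones grow around each area centroid by
ascending centroid distance until the next area would push the zone
past `max_fraction` (default 0.5) of the total expected count.  The
statistic is the Poisson log-likelihood ratio
$Y_z \log(Y_z/E_z) + (Y_t - Y_z)\log((Y_t-Y_z)/(E_t-E_z))$ for
high-rate zones, with expectations conditioned on the observed total,
and inference by multinomial redistribution of the total over areas
(999 replicates by convention).  Elliptical windows, space-time scans
and secondary-cluster reporting are out of scope; window shape is
orthogonal to the statistic.

## Mapping defaults

Seven classes with default breaks
$(0, 0.5, 0.75, 0.95, 1.05, 1.33, 2, \infty)$ — the near-unity class
is $[0.95, 1.05)$ — half-open intervals, clamping outside the range,
undefined SIRs unclassified.  On raw maps the significance flag marks
areas whose exact interval excludes 1; on smoothed maps the analogue
is the exceedance flag at the conventional 0.80 cut.  Both the breaks
and the cut are configuration, since published breakpoints vary by
atlas.

## Simulation sizes

The test-suite and acceptance-script runs use sizes chosen to make
Monte-Carlo noise small relative to the bands being checked while
keeping a laptop-scale run: bootstrap type-I error over 500 null
datasets on a 10×10 lattice at $E = 10$ with $B = 199$; BYM parameter
recovery on a 10×10 lattice at $E = 20$ with 2 chains × 5,000 saved
draws; exceedance sensitivity over 20 replicates of a 3×3 doubled-risk
block at $E = 20$; scan null calibration over 200 datasets at 7×7; the
end-to-end pipeline at the full 331-area scale with a doubled-risk
cluster of graph radius 2.

## Known limitations

* The single-site Metropolis sampler is exact but not the fastest
  mixer for strongly coupled fields; the heavyweight `"replica"`
  protocol exists for final analyses.  Exact bit-level invariance of
  the fit under area relabelling is not attainable with a single RNG
  stream and fixed sweep order; relabelling reproduces summaries to
  Monte-Carlo error (tested).
* Exceedance probabilities at very small expected counts
  ($E \lesssim 5$) are dominated by the prior and shrink toward the
  field mean; detection of single elevated areas is weak there by
  design of the BYM model — clusters of areas are the detectable unit.
* No spatio-temporal or shared-component extensions, no alternative
  spatial priors (Leroux, BYM2), no INLA-style approximations.
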