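---
title: "Modelling distance decay in fever treatment seeking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling distance decay in fever treatment seeking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`feverseek` estimates the probability that a child with fever is taken to
a public-sector health facility, as a function of travel time and
residence, from household-survey microdata. This vignette is the package's
account of the science: the model and its assumptions, the choices made
where the design was genuinely open, what the synthetic-data generator
does and does not emulate, and the numerical details a careful user should
know.

## The statistical model

The observed outcome is a single dichotomous survey item per fever
episode: treatment sought in the public sector or not. We model it with a
unidimensional three-parameter logistic (3PL) item-response model,

$$P(Y_{ij} = 1 \mid \theta_j, a_i, b_i, c_i)
  = c_i + (1 - c_i)\,
    \frac{e^{a_i \theta_j - b_i}}{1 + e^{a_i \theta_j - b_i}},$$

with discrimination $a_i > 0$, difficulty $b_i$, and floor
$c_i \in (0, 1]$. The floor is the scientifically interesting parameter:
it is the asymptotic minimum probability of seeking treatment, the level
the curve approaches for households living arbitrarily far from care. The
latent ability of child $j$'s household to seek treatment is a
deterministic linear function of its geography,

$$\theta_j = \alpha + \beta_{\text{time}}\, t_j + \beta_{\text{urban}}\,
  \mathbb{1}[\text{urban}_j],$$

where $t_j$ is travel time in minutes to the nearest public facility.
There is no child-level residual in $\theta_j$: with a single binary
response per child, an individual noise term is not identified, so two
children in the same cluster share the same ability. Distance decay
corresponds to $\beta_{\text{time}} < 0$.

**Identifiability.** With one item, $(a, b)$ are confounded with the scale
and location of $\theta$ — rescaling $a$ can be absorbed into
$(\alpha, \beta)$, and $b$ into $\alpha$. `fit_treatment_irt()` therefore
fixes $a = 1$, $b = 0$ by default in the single-item configuration and
estimates them only in the multi-item (per-facility-tier) configuration,
where the first item is the anchor. Any parameter can be pinned explicitly
through the `fix` argument, which is also how the reduced models used as
oracles in the tests are constructed.

**Priors.** Defaults, all configurable via `prior_spec()`:
$a \sim N(0, 2.5^2)$ truncated to $(0, \infty)$; $c \sim \text{Beta}(2, 5)$,
a weak preference for small floors with full support on $(0, 1)$;
$b, \alpha \sim N(0, 5^2)$; the slopes $\sim N(0, 1)$ *on the per-hour
scale* — travel time is divided by 60 inside the sampler so that a
unit-variance prior is weakly informative for plausible decay strengths
(the user-facing `beta_time` is always per minute). Missing treatment
responses ("don't know") are dropped from the likelihood, which is the
correct treatment under missingness at random; they are never imputed for
parameter inference.

## Posterior computation

The posterior $f(\theta, a, b, c \mid y) \propto L(y \mid \theta, a, b, c)
f(\theta, a, b, c)$ is sampled with a Metropolis-within-Gibbs scheme
written for this package:

* block 1: the free ability coefficients, updated jointly by a Gaussian
  random walk;
* per item: $(\log a_i, b_i)$ jointly, and $\operatorname{logit} c_i$
  separately, with the log/logit transforms keeping every proposal inside
  the support (the Jacobians are included in the target).

Proposal scales adapt by a Robbins–Monro rule every 50 iterations *during
burn-in only*, towards 30% acceptance (the retained phase runs with frozen
scales, so the chains target the exact posterior). Chains start from
over-dispersed jittered positions. The likelihood is evaluated on data
aggregated to binomial sufficient statistics per unique (item, travel
time, residence) combination — algebraically identical to the child-level
product and much faster, since covariates vary at cluster level.

The default desk schedule is 22,000 iterations, 2,000 burn-in, thinning
10, three chains (2,000 retained draws per chain, a few seconds to a
minute depending on data size). A production schedule of 550,000
iterations with 50,000 burn-in and thinning 500 — three chains, exactly
1,000 retained draws each — is available by explicit configuration;
nothing in the code depends on which schedule is used.

Convergence is reported as the Gelman–Rubin potential scale reduction
factor, in the classic uncorrected form
$\sqrt{((n-1)/n\,W + B/n)/W}$, together with the Raftery–Lewis run-length
diagnostic (binarisation at the target quantile, BIC-selected Markov
thinning, two-state transition estimates); the independent-chain minimum
$N_{\min} = \lceil z^2 q(1-q)/r^2 \rceil$ equals 3,746 for
$(q, r, s) = (0.025, 0.005, 0.95)$. Both are cross-checked against `coda`
in the test suite but implemented independently.

## Travel time

Travel time is computed on a friction surface: each cell carries a speed
in km/h from its land class (walking, slope-corrected) or the motorised
road speed. The slope correction is the Tobler hiking factor normalised
to flat ground, $v(s) = v_{\text{flat}}\, e^{-3.5|s + 0.05|}/e^{-0.175}$,
evaluated at the cell's steepest slope magnitude over its eight
neighbours. Design choices, made where accessibility tools differ:

* **Isotropic costs.** Direction-dependent (anisotropic) slope costs would
  make edge weights asymmetric; we use a scalar per-cell correction, which
  keeps the graph symmetric and the engine testable against a path
  enumeration oracle.
* **Edge cost** between adjacent cells is centre-to-centre distance
  (diagonals $\times \sqrt 2$; 8-connectivity, no knight's moves) divided
  by the *harmonic mean* of the two cell speeds — the exact travel time if
  half the distance is covered at each speed.
* Facilities snap to their containing cell centre; several facilities in
  one cell collapse to a single source; the output is the exact minimum
  over all paths to any source (multi-source Dijkstra, via `igraph`).

Default walking speeds (grassland 5, cropland 4.5, forest 3, wetland
1.5 km/h; roads 60 km/h motorised) are a documented convention, not an
estimate; every speed is configurable.

## The synthetic study

`generate_landscape()`, `sample_clusters()`, `displace_clusters()` and
`simulate_responses()` produce a complete survey world with known ground
truth. They emulate the features of the real sampling design that matter
for this model:

* two-stage cluster sampling with probability-proportional-to-size
  selection of cluster cells (weighted sampling *without* replacement, so
  cluster locations are distinct), 15–30 households per cluster, one
  under-5 child per household;
* a two-week fever recall outcome, treatment responses drawn from the 3PL
  model at the cluster's travel time and residence, and a
  missing-at-random share of "don't know" responses among fever cases;
* disclosure-protection displacement of cluster coordinates: uniform
  angle, uniform distance up to 2 km (urban) or 5 km (rural), with 1% of
  rural clusters displaced up to 10 km — the convention used by the major
  georeferenced survey programmes, since published magnitudes, not
  mechanisms, are what an analyst faces. Responses are simulated at the
  *published* coordinates so the generative model and the fitted model
  agree by construction; the retained true coordinates let a user inject
  covariate measurement error deliberately.

It does **not** emulate real administrative boundaries (the partition is a
regular block tiling), real population surfaces (population is a smooth
town-kernel mixture), survey non-sampling error, seasonality, multiple
treatment sources per episode, or private-sector competition. Passing
tests therefore demonstrate that the estimator recovers the model's own
parameters under the stated design — not that the model is correctly
specified for any particular country's data.

## Back-calculated surfaces and validation

Treatment curves, threshold tables, probability maps and holdout
predictions are all computed *draw-wise*: the 3PL probability is evaluated
at every retained draw and then summarised per point by the median and
central 95% interval (linear-interpolation quantiles). Evaluating instead
at the posterior medians of the parameters ("plug-in") yields no valid
band and a slightly different centre because the probability is a
nonlinear map; a plug-in mode exists behind a flag for comparison. The
draw-wise median curve inherits the floor: every draw satisfies
$P(t) > c$, so the curve approaches the posterior median of $c$ from
above as travel time grows.

Validation reserves a random 10% of children with observed responses
(stratified by survey when several are present); the fitted model's
posterior-median probabilities are binarised at 0.5 (the cutoff is
configurable — the convention is stated nowhere authoritative) for the
misclassification error, and the ROC is swept over unique scores with
trapezoidal AUC, which equals the Mann–Whitney pair-count statistic
including under ties. Aggregation reports, per admin unit, the observed
treated fraction among fever cases with observed responses scaled to a
per-1,000-under-5 rate, and a population-weighted national mean.

## Numerical details and test scale

* Quantiles everywhere are R's default type-7 (linear interpolation).
* `item_probability()` uses `plogis` and is stable to $|a\theta - b|$ of
  several hundred; degenerate likelihood corners (e.g. $p = 1$ with
  observed failures) return $-\infty$ rather than `NaN`.
* Land-class patches are produced by quantile-slicing a smooth random
  field, so configured class fractions are met exactly up to cell
  rounding; a tiny white-noise dither breaks ties deterministically under
  the seed.
* Displacement clamping to the study extent is a projection onto a convex
  set, so it can only shrink displacement distances and the documented
  bounds survive.
* All randomness flows through per-stage substreams of one master seed;
  re-running any stage with the same configuration is bit-reproducible,
  and changing reporting settings (thresholds, holdout fraction) never
  perturbs the simulated survey or the travel-time surface.
* Problem sizes used by the test suite, chosen as the smallest that
  exercise each property cleanly: path-enumeration oracles on grids up to
  5×5; quadrature oracle on 20 observations with an 8,001–20,001-point
  grid; parameter recovery on 20 replicates of 5,000 fever cases across
  100 clusters with travel times spread over 0–480 minutes (the long tail
  is what identifies the floor $c$); ROC identity on 100 random instances
  of up to 200 scores.

## Known limitations

With cluster-level covariates and one binary response per child,
individual-level predictive discrimination is intrinsically modest
(holdout AUC well below one even under the true model); the model's value
is the population-level curve, not per-child prediction. The floor $c$ is
weakly identified when the survey contains no clusters far from
facilities — its posterior then leans on the Beta(2, 5) prior. The
travel-time engine is a desk-scale isotropic approximation and does not
reproduce the output of full anisotropic accessibility software. Per-item
person coefficients are not estimable from single responses and are
deliberately shared across children.
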