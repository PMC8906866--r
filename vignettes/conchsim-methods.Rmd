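---
title: "Modelling queen conch reproductive dynamics with conchsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling queen conch reproductive dynamics with conchsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conchsim)
```

## The scientific problem

Queen conch (*Lobatus gigas*) reproduce by internal fertilisation: a male
must physically reach a receptive female.  Because adults crawl only a few
metres per day, the chance of finding a mate collapses as aggregation
density falls, and field surveys report little or no mating below a
critical density — a depensatory (Allee) effect that is a leading
hypothesis for why heavily fished conch populations fail to recover.
`conchsim` implements an individual-based model of this process: adults
move daily in a one-hectare arena, encounters between daily paths produce
matings subject to behavioural gates, and matings produce delayed
egg-deposition (spawning) events.  The emergent percent-mating and
percent-spawning versus density curves can then be compared against
survey-style observations through censored dose-response regression and
goodness-of-fit superiority tests.

## The model, step by step

Each simulated day, for every adult:

1. **Perception.** A perception distance is drawn from U(0, `pd_max`)
   (`pd_max` in {0.5, 1.5, 3} m).  Resampling daily represents day-to-day
   variation in visibility, currents, and microhabitat, not a fixed
   individual trait.
2. **Movement.** Speed is drawn from a truncated normal (three presets
   estimated from telemetry: low 2.57 ± 1.57 m/d on [1.47, 3.56]; medium
   4.17 ± 0.41 on [0, 5.52]; high 11.36 ± 0.24 on [0, 21.24]) and
   direction from U(0°, 360°) — an isotropic simple random walk with no
   day-to-day persistence.
3. **Scent tracking (optional).** Conspecifics within 22 m attract the
   focal animal with per-pair magnitude `strength / max(d, 1 m)`; the
   contributions are summed (Barnes–Hut approximation with `theta = 0.9`
   for large populations) and the net daily taxis displacement is capped
   at 22 m.  The displacement is added to the random step.
4. **Constraints.** The proposed step is resolved against the barrier (if
   any), then folded back into the arena by mirror reflection at the
   walls.
5. **Encounters and mating.** Opposite-sex pairs whose daily path
   segments pass within the *larger* of their two perception distances
   have an encounter.  Every encounter increments both contact counters.
   A mating occurs when the female is receptive (not in a post-mating
   rest period), has not already mated today, and the sexual-facilitation
   gate `U(0,1) < min(1, C/τ)` passes, where `C` is her cumulative contact
   count and τ in {0, 5, 10, 25, 50} (τ = 0 disables the gate).  After a
   mating she becomes unreceptive for `1 + rest` days, with rest drawn
   from the active rest scenario (0; U(0, 2); or 8.7 ± 4.9 d truncated to
   [0, 24.83]).
6. **Spawning.** Each mated female spawns after oogenesis delays drawn
   from the 8.7 ± 4.9 d (0–24.83) truncated normal, chained from her
   first mating; no re-mating is needed (females store sperm).  Spawns
   past the 10-day season are discarded.

A run reports the percent of adults with at least one mating and the
percent of adults that spawned (all-adult denominator).  Ten replicates
per design point are aggregated as mean ± Student-t 95% interval.

## Design choices where the design was genuinely open

Several details are not fixed by the biology and had to be decided once:

* **Encounter rule.** "Within the randomly selected perception distance
  for those individuals" could mean either-perceives (max), both (min),
  or something asymmetric.  We use the **max**: one individual noticing
  the other is enough to close a sub-metre gap.  `min` and `mean` remain
  easy to add but are not exposed as of this version.
* **Metric.** Percent mating is **cumulative over the 10-day run** by
  default (`daily_mean` is available), matching the magnitudes of the
  simulated curves; instantaneous field surveys are closer to the daily
  mean, which is one reason simulations sit above survey points.
* **Sex ratio** is 50:50 with females = ⌈N/2⌉; the literature does not
  fix it.
* **One mating per female per day; males unlimited.** Only female
  receptivity is restricted by the biology we model.  The within-day
  processing order of encounters is shuffled with the run RNG so low ids
  get no systematic advantage.
* **Facilitation contacts** accumulate from *encounters* (not matings),
  including repeated contacts with the same male, across the whole
  season; the gate is evaluated per encounter using the count that
  includes the current contact.
* **Arena closure.** The walls reflect.  Reflection preserves density,
  whereas absorbing or wrapping boundaries would change the effective
  density being simulated.
* **Barrier geometry.** The single linear barrier is a thin 1 m × 80 m
  rectangle centred at (50, 50) along the y-axis: it blocks 80% of the
  crossing dimension, leaving 10 m gaps at the arena edges.  Crossings
  are blocked, not just endpoints-inside — a zero-width wall that could
  be jumped would restrict nothing; offending endpoints are relocated to
  the nearest exterior point on the start's side.
* **Attraction force.**  The tracking force follows the charge-like
  `strength/d` law of d3-style many-body forces, with the d3 default
  1 m minimum-distance clamp.  The strength is nowhere published, so the
  default (6.425 m²/d) is calibrated from a physical anchor: a lone pair
  5 m apart closes their gap at the low-scenario mean speed
  (2 × 6.425 / 5 = 2.57 m/d).  The net daily taxis displacement is capped
  at the 22 m influence radius — an animal cannot out-travel in one day
  the range over which it can smell.  All of these are configuration
  fields, not constants.
* **Seeding.**  Replicate seeds derive from
  `(base_seed, design_index, replicate_index)` via Cantor pairing plus
  bijective odd-multiplier scrambling modulo 2^31, carried out entirely
  below 2^53 in doubles.  This is exact and identical on every platform,
  and injective across the design, which R's 32-bit integers would make
  awkward for 64-bit mixing schemes.

## The comparison stage

Simulated mean percent-mating curves are interpolated linearly on the
log10-density axis (the axis on which the curves are drawn and close to
linear; a linear-density axis is available via `log_axis = FALSE`) at the
observed densities.  Observations are censored before regression:
zero-mating records above 100 adults/ha are dropped (`censor_mating()`),
and spawning-without-mating records are dropped for the mating-spawning
relationship (`censor_spawn_vs_mating()`).  The reference regression is a
three-parameter log-logistic with lower limit 0,

f(x) = d / (1 + exp(b (ln x − ln e))),

fitted by multi-start Levenberg–Marquardt least squares (starts
b₀ ∈ {−1, −5, −50}, d₀ = max y, e₀ = x at half-maximum) because fitted
slopes can exceed |b| ≈ 50, which defeats single-start optimisers.  The
mating–spawning relationship uses the two-parameter asymptotic model
d (1 − exp(−x/e)).  Standard errors come from the Jacobian at the
optimum; t and p values use df = n − (number of parameters).

Goodness of fit is summarised as SSR, MSE = SSR/n, RMSE = √MSE.  A
mechanistic simulation is *superior* when its SSR is strictly below the
regression's (ties are not superior).  "Paired t-tests assuming unequal
variances" is internally contradictory, so the primary significance test
is a paired t-test on absolute residuals (pairing matches the shared
observations; magnitudes match the fit-quality question), with a Welch
two-sample variant selectable; thresholds are Bonferroni-corrected
(α/m).

## The synthetic observation generator

The real survey datasets behind the published comparisons are not
publicly deposited, so `fixture_spec()`/`generate_observations()`
generate survey-like tables from known curves: percent mating from a
log-logistic curve (presets: a Bahamas-like steep curve with asymptote
10.16% and ED50 64.35 adults/ha, and a Florida-like curve with asymptote
10.43% and ED50 204.83), Gaussian noise (default SD 2 percentage
points), optional zero inflation below 100 adults/ha (default rate 0.1,
reflecting how often sparse-site surveys record no activity), and paired
percent spawning from an asymptotic curve of the realised mating
percentage.  These fixtures exercise every comparison-stage code path
and let tests verify parameter recovery, but they deliberately lack
features of real surveys — spatial autocorrelation, observer effects,
methodological differences between transect designs — so passing tests
demonstrate correctness of the machinery, not field realism.

One identifiability caveat matters when building fixtures: with slopes as
steep as the survey fits (|b| ≈ 56–71), the mating curve is effectively a
step between adjacent levels of the ten-density grid, so observations at
only those levels bracket the ED50 without identifying it (and Jacobian
standard errors degenerate).  Recovery tests therefore sample
survey-style continuous densities, which also better emulates the field
datasets; and a mechanism-recovery study must use generating curves
*outside* the log-logistic family (e.g. double sigmoids), because least
squares fitted to the shared observations can never have a larger SSR
than a curve inside its own family.

## Numerical choices and degenerate inputs

* Truncated normals are sampled by inverse CDF (`qnorm` of a uniform on
  the truncated probability range); `sd = 0` returns the mean exactly.
* Segment–segment distances use the clamped closest-point algorithm;
  encounter detection pre-filters pairs with a bounding-circle test and
  is verified against an all-pairs brute force.
* Barnes–Hut cells are aggregated only when the opening criterion
  `w/l < 0.9` holds *and* the cell lies entirely inside the 22 m cutoff;
  cells entirely outside are skipped.  Cutoff membership is therefore
  exact and only the centre-of-mass grouping approximates (relative
  error ≲ 5% up to 2500 agents).
* Coincident agents contribute no attraction (the pair is skipped).
* Nonlinear fits that fail from every start return a flagged
  non-convergent object rather than an error mid-pipeline.
* A drawn spawn delay of exactly 0 spawns on the mating day and ends the
  schedule, preventing an infinite same-day spawn chain.
* After wall reflection an endpoint can in rare geometries land inside
  the barrier; it is then moved to the nearest barrier-exterior point.

## Problem sizes used in the test suite

The shipped tests run the study conditions at reduced scale chosen for a
single workstation: replicate counts of 6–12 for curve-shape checks, 200
replicates per arm for the low-density scent-tracking contrast, 30–40
per arm at 2500 adults/ha, and property suites over populations up to
2500 agents and 10⁵ movement updates.  The full published design (43,200
runs) is reproducible with `run_design()` on the full
`build_design_grid()` but is a cluster-scale computation; the package's
`design_totals()` reproduces its bookkeeping exactly.

## Known limitations

* At 2500 adults/ha with all factors at their lowest levels, essentially
  every adult's daily path passes within perception range of an
  opposite-sex path during a 10-day season, so cumulative percent mating
  saturates near 100% with tracking either on or off.  The published
  observation that scent tracking slightly *reduces* high-density mating
  (a "confusion effect") arises from velocity-integrator particle
  dynamics that this model's daily-chord encounter geometry does not
  reproduce; `conchsim` reports the honestly computed (near-zero) effect
  at that density.
* Correlated random walks, multiple/complex barrier layouts, depth or
  habitat structure, tidal advection, sperm depletion, and egg counts
  per mass are out of scope.
* The facilitation gate is linear in contacts; field data hint a
  knife-edge threshold may fit better.

## A worked example

```{r example, eval = FALSE}
library(conchsim)

# one design point: 250 adults/ha, medium speed, facilitation tau = 10
dp <- design_point(250,
                   speed = speed_scenario("med"),
                   facilitation = facilitation_scenario(10),
                   design_index = 1L)
rs <- run_replicates(dp, run_config(base_seed = 1))
rs

# a small density sweep and comparison against synthetic observations
grid <- build_design_grid(speeds = "low", rests = "zero",
                          tracking = FALSE, pd_max = 0.5, tau = 0,
                          barriers = "none")
res <- run_design(grid, run_config(base_seed = 1))
obs <- generate_observations(fixture_spec("bahamas", seed = 1))
fraction_superior(res, obs)$pct_superior
```
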