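# conchsim

Individual-based simulation of queen conch (*Lobatus gigas*) mating and
spawning dynamics, with a dose-response comparison stage.

## Why

Queen conch must be in physical contact to mate, crawl only metres per
day, and aggregate to spawn.  Field surveys across the Caribbean report
a depensatory (Allee) pattern: below a critical adult density almost no
mating or egg laying is observed, which is a leading explanation for why
fished-down populations fail to recover.  `conchsim` is for population
ecologists and fishery scientists who want to ask *which mechanisms are
sufficient to produce that pattern*: it simulates adults moving through
a one-hectare arena day by day and measures how density, movement speed,
interbreeding rest periods, scent tracking, perception distance, sexual
facilitation, and movement barriers shape the percentage of the
population that mates and spawns.

## The model in brief

Each day every adult draws a speed from a truncated normal (three
telemetry-based scenarios), a direction from U(0°, 360°) (an isotropic
simple random walk), and a perception distance from U(0, pd_max).
Optional scent tracking adds a bounded attraction toward conspecifics
within 22 m (charge-like `strength/d` pairwise law, Barnes-Hut
approximated with θ = 0.9 at scale).  Steps are resolved against a
central barrier and reflecting arena walls.  An encounter is an
opposite-sex pair whose daily paths pass within the larger of their two
perception distances; a mating requires the female to be receptive (not
in a post-mating rest period), unmated today, and to pass the
sexual-facilitation gate

    U(0,1) < min(1, C / tau)

where `C` is her cumulative contact count.  Mated females spawn after
oogenesis delays drawn from a truncated normal 8.7 ± 4.9 d (0–24.83).
Simulated percent-mating curves are compared with observation tables via
censored three-parameter log-logistic regression
`f(x) = d / (1 + exp(b (ln x − ln e)))` (lower limit 0, ED50 `e`),
asymptotic regression `d (1 − exp(−x/e))` for mating vs spawning,
SSR/MSE/RMSE goodness of fit, and Bonferroni-corrected paired t-tests on
residuals.

## A worked example

```r
library(conchsim)

dp <- design_point(250,
                   speed = speed_scenario("med"),
                   facilitation = facilitation_scenario(10),
                   design_index = 1L)
run_replicates(dp, run_config(base_seed = 1))
#> design 1 (density 250, 10 reps): mating 33.1% [30.5, 35.8], spawning 3.0% [2.3, 3.8]
```

At 250 adults/ha with medium speed and a facilitation threshold of 10
prior contacts, about a third of adults mate at least once in the 10-day
season and 3% of adults deposit an egg mass (spawning lags mating
because of the 8.7 ± 4.9 d oogenesis delay inside a 10-day season); the
brackets are Student-t 95% intervals across the 10 replicates.  Dropping
the density to 25 adults/ha under the same settings collapses mating to
5.6% [1.7, 9.5] — the depensatory pattern the model exists to study.

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/conchsim.R totals --runs 43200 --days 10
# {"spawning_days":432000,"individuals":20671200}
Rscript inst/scripts/conchsim.R fixtures --out obs.csv --seed 1
Rscript inst/scripts/conchsim.R run --density 100 --replicates 10 --seed 1
```

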