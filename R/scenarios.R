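#' Table of simulated adult densities
#'
#' The ten adult densities (adults per hectare) used across the factorial
#' design, spanning the range reported for wild queen conch aggregations.
#'
#' @return Numeric vector of densities (adults/ha).
#' @export
conch_densities <- function() {
  c(10, 25, 50, 100, 150, 200, 250, 500, 1000, 2500)
}

#' Movement-speed scenario
#'
#' Daily movement speed is drawn from a truncated normal distribution.  The
#' three presets correspond to field-derived estimates: `"low"` from male
#' within-aggregation speeds, `"med"` from summer speeds, `"high"` from
#' pre-aggregation migratory movements.
#'
#' @param level One of `"low"`, `"med"`, `"high"`, or `"custom"`.
#' @param mean,sd,lo,hi Truncated-normal parameters in m/day; required when
#'   `level = "custom"`, ignored otherwise.
#' @return An object of class `conch_speed` with fields `label`, `mean`,
#'   `sd`, `lo`, `hi`.
#' @examples
#' speed_scenario("low")
#' @export
speed_scenario <- function(level = c("low", "med", "high", "custom"),
                           mean = NULL, sd = NULL, lo = NULL, hi = NULL) {
  level <- match.arg(level)
  presets <- list(
    low  = c(mean = 2.57,  sd = 1.57, lo = 1.47, hi = 3.56),
    med  = c(mean = 4.17,  sd = 0.41, lo = 0,    hi = 5.52),
    high = c(mean = 11.36, sd = 0.24, lo = 0,    hi = 21.24)
  )
  if (level == "custom") {
    if (is.null(mean) || is.null(sd) || is.null(lo) || is.null(hi))
      stop("custom speed scenario requires mean, sd, lo and hi")
    p <- c(mean = mean, sd = sd, lo = lo, hi = hi)
  } else {
    p <- presets[[level]]
  }
  if (p[["lo"]] > p[["hi"]]) stop("speed scenario: lo > hi")
  if (p[["sd"]] < 0) stop("speed scenario: sd must be >= 0")
  if (p[["mean"]] < p[["lo"]] || p[["mean"]] > p[["hi"]])
    stop("speed scenario: mean outside [lo, hi]")
  structure(list(label = level, mean = p[["mean"]], sd = p[["sd"]],
                 lo = p[["lo"]], hi = p[["hi"]]),
            class = "conch_speed")
}

#' Interbreeding rest-period scenario
#'
#' Duration (days) during which a female is unreceptive after a mating
#' event.  `"zero"` means no rest, `"uniform"` draws U(0, 2) days, and
#' `"truncnorm"` draws from the 8.7 +/- 4.9 d (0-24.83) oogenesis-based
#' distribution.
#'
#' @param kind One of `"zero"`, `"uniform"`, `"truncnorm"`.
#' @return Object of class `conch_rest`.
#' @export
rest_scenario <- function(kind = c("zero", "uniform", "truncnorm")) {
  kind <- match.arg(kind)
  params <- switch(kind,
    zero = list(),
    uniform = list(lo = 0, hi = 2),
    truncnorm = list(mean = 8.7, sd = 4.9, lo = 0, hi = 24.83))
  structure(list(kind = kind, params = params), class = "conch_rest")
}

#' Scent-tracking scenario
#'
#' When enabled, conch are attracted to conspecifics within
#' `max_taxis_distance` with per-pair magnitude
#' `strength / max(d, distance_min)` directed toward the neighbour, summed
#' over neighbours.  The net daily taxis displacement is capped at
#' `max_taxis_distance` (an animal cannot out-travel the scent range in a
#' day).  `theta` controls the Barnes-Hut opening criterion used for large
#' populations.  The default `strength` is calibrated so a lone male-female
#' pair 5 m apart closes their gap at the low-scenario mean speed
#' (2.57 m/day): 2 * strength / 5 = 2.57.
#'
#' @param enabled Logical; disabled tracking contributes zero displacement.
#' @param max_taxis_distance Influence radius and daily taxis cap, m.
#' @param duration Taxis memory in days (fixed at the 1-day time step).
#' @param theta Barnes-Hut accuracy parameter (dimensionless).
#' @param strength Attraction scale (m^2/day).
#' @param distance_min Distance clamp for the force law, m.
#' @param same_sex_excluded Logical; when `TRUE` attraction acts only
#'   between opposite sexes.
#' @return Object of class `conch_tracking`.
#' @export
tracking_scenario <- function(enabled = FALSE, max_taxis_distance = 22,
                              duration = 1, theta = 0.9,
                              strength = 6.425, distance_min = 1,
                              same_sex_excluded = FALSE) {
  stopifnot(is.logical(enabled), length(enabled) == 1L,
            max_taxis_distance > 0, theta > 0, strength >= 0,
            distance_min > 0, duration > 0)
  structure(list(enabled = enabled, max_taxis_distance = max_taxis_distance,
                 duration = duration, theta = theta, strength = strength,
                 distance_min = distance_min,
                 same_sex_excluded = isTRUE(same_sex_excluded)),
            class = "conch_tracking")
}

#' Perception-distance scenario
#'
#' Each individual's daily perception distance is drawn from
#' U(0, `pd_max`), representing day-to-day variation in visibility,
#' currents, and benthic habitat.  Simulated levels are 0.5, 1.5, 3.0 m.
#'
#' @param pd_max Upper bound of the uniform perception-distance
#'   distribution, m.
#' @return Object of class `conch_perception`.
#' @export
perception_scenario <- function(pd_max = 0.5) {
  stopifnot(is.numeric(pd_max), length(pd_max) == 1L, pd_max > 0)
  structure(list(pd_max = pd_max, distribution = "uniform"),
            class = "conch_perception")
}

#' Sexual-facilitation scenario
#'
#' The probability a receptive female accepts a mating attempt rises
#' linearly with her cumulative count of opposite-sex contacts C, reaching
#' 1 at `tau` contacts: pass iff U(0,1) < min(1, C / tau).  `tau = 0`
#' disables the requirement (the gate always passes).
#'
#' @param tau Number of prior interactions required for certain mating.
#' @return Object of class `conch_facilitation`.
#' @export
facilitation_scenario <- function(tau = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("tau must be a single non-negative number")
  structure(list(tau = tau), class = "conch_facilitation")
}

#' Barrier scenario
#'
#' `"one"` places a single thin linear barrier centred in the arena,
#' spanning 80% of the crossing dimension (for a 100 m arena: a 1 m x 80 m
#' rectangle centred at (50, 50) oriented along y, leaving 10 m gaps at
#' both arena edges).
#'
#' @param kind `"none"` or `"one"`.
#' @param arena_side Arena side length, m; defines the barrier geometry.
#' @param orientation Long-axis orientation of the barrier.
#' @return Object of class `conch_barrier`; for `kind = "one"` it carries a
#'   `rect` field `c(xmin, xmax, ymin, ymax)`.
#' @export
barrier_scenario <- function(kind = c("none", "one"), arena_side = 100,
                             orientation = c("vertical", "horizontal")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  rect <- NULL
  if (kind == "one") {
    half_w <- 0.5          # 1 m thick wall
    span <- 0.8 * arena_side
    c0 <- arena_side / 2
    if (orientation == "vertical") {
      rect <- c(xmin = c0 - half_w, xmax = c0 + half_w,
                ymin = c0 - span / 2, ymax = c0 + span / 2)
    } else {
      rect <- c(xmin = c0 - span / 2, xmax = c0 + span / 2,
                ymin = c0 - half_w, ymax = c0 + half_w)
    }
  }
  structure(list(kind = kind, orientation = orientation,
                 arena_side = arena_side, rect = rect),
            class = "conch_barrier")
}

#' A single design point of the factorial experiment
#'
#' Bundles a density with one level of each mechanistic factor.
#'
#' @param density Adults per hectare; must be one of [conch_densities()]
#'   unless `allow_free_density = TRUE`.
#' @param speed,rest,tracking,perception,facilitation,barrier Scenario
#'   objects (see the respective constructors).
#' @param design_index Integer identifier within a design grid (used to
#'   derive replicate seeds).
#' @param allow_free_density Permit densities outside the standard grid.
#' @return Object of class `conch_design_point`.
#' @export
design_point <- function(density,
                         speed = speed_scenario("low"),
                         rest = rest_scenario("zero"),
                         tracking = tracking_scenario(FALSE),
                         perception = perception_scenario(0.5),
                         facilitation = facilitation_scenario(0),
                         barrier = barrier_scenario("none"),
                         design_index = 1L,
                         allow_free_density = FALSE) {
  stopifnot(inherits(speed, "conch_speed"), inherits(rest, "conch_rest"),
            inherits(tracking, "conch_tracking"),
            inherits(perception, "conch_perception"),
            inherits(facilitation, "conch_facilitation"),
            inherits(barrier, "conch_barrier"))
  if (!allow_free_density && !density %in% conch_densities())
    stop("density ", density, " is not a standard level; ",
         "use allow_free_density = TRUE to override")
  if (density <= 0) stop("density must be positive")
  structure(list(density = density, speed = speed, rest = rest,
                 tracking = tracking, perception = perception,
                 facilitation = facilitation, barrier = barrier,
                 design_index = as.integer(design_index)),
            class = "conch_design_point")
}

#' Run configuration
#'
#' Arena, season length, replicate count, the oogenesis spawn-delay
#' distribution, the reporting metric, and the base seed from which all
#' per-run seeds are derived.
#'
#' @param arena_side Arena side, m (100 m = 1 ha).
#' @param days Season length in daily steps.
#' @param replicates Replicate runs per design point.
#' @param spawn_delay Truncated-normal parameters (days) of the delay
#'   between a mating (or previous spawn) and egg deposition.
#' @param mating_metric `"cumulative"` (percent of adults with at least one
#'   event over the run) or `"daily_mean"` (mean over days of the percent
#'   mating that day).
#' @param base_seed Integer base seed.
#' @return Object of class `conch_config`.
#' @export
run_config <- function(arena_side = 100, days = 10, replicates = 10,
                       spawn_delay = list(mean = 8.7, sd = 4.9,
                                          lo = 0, hi = 24.83),
                       mating_metric = c("cumulative", "daily_mean"),
                       base_seed = 1L) {
  mating_metric <- match.arg(mating_metric)
  stopifnot(arena_side > 0, days >= 1, replicates >= 1)
  structure(list(arena_side = arena_side, days = as.integer(days),
                 replicates = as.integer(replicates),
                 spawn_delay = spawn_delay, mating_metric = mating_metric,
                 base_seed = as.integer(base_seed)),
            class = "conch_config")
}

#' Build the factorial design grid
#'
#' Cartesian product of the supplied factor levels, ordered
#' deterministically with density outermost (slowest varying), then speed,
#' rest, tracking, perception, facilitation, and barrier innermost.  The
#' row order defines `design_index`, from which replicate seeds derive.
#'
#' @param densities Adult densities (adults/ha).
#' @param speeds Speed levels (subset of `"low"`, `"med"`, `"high"`).
#' @param rests Rest-period kinds.
#' @param tracking Logical vector of tracking states.
#' @param pd_max Perception-distance upper bounds, m.
#' @param tau Sexual-facilitation thresholds.
#' @param barriers Barrier kinds.
#' @param allow_free_density Permit non-standard densities.
#' @return A data.frame with one row per design point and columns
#'   `design_index`, `density`, `speed`, `rest`, `tracking`, `pd_max`,
#'   `tau`, `barrier`.
#' @examples
#' nrow(build_design_grid())  # 5400 for the full factorial
#' @export
build_design_grid <- function(densities = conch_densities(),
                              speeds = c("low", "med", "high"),
                              rests = c("zero", "uniform", "truncnorm"),
                              tracking = c(FALSE, TRUE),
                              pd_max = c(0.5, 1.5, 3.0),
                              tau = c(0, 5, 10, 25, 50),
                              barriers = c("none", "one"),
                              allow_free_density = FALSE) {
  lv <- list(densities = densities, speeds = speeds, rests = rests,
             tracking = tracking, pd_max = pd_max, tau = tau,
             barriers = barriers)
  bad <- names(lv)[vapply(lv, length, 1L) == 0L]
  if (length(bad))
    stop("every factor needs at least one level; empty: ",
         paste(bad, collapse = ", "))
  if (!allow_free_density && !all(densities %in% conch_densities()))
    stop("non-standard density level; use allow_free_density = TRUE")
  g <- expand.grid(barrier = barriers, tau = tau, pd_max = pd_max,
                   tracking = tracking, rest = rests, speed = speeds,
                   density = densities,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("density", "speed", "rest", "tracking", "pd_max", "tau",
             "barrier")]
  g <- data.frame(design_index = seq_len(nrow(g)), g,
                  stringsAsFactors = FALSE)
  rownames(g) <- NULL
  g
}

#' Reconstruct a design point from one grid row
#'
#' @param row A one-row data.frame as produced by [build_design_grid()].
#' @param arena_side Arena side, m (needed for the barrier geometry).
#' @return A `conch_design_point`.
#' @export
design_point_from_row <- function(row, arena_side = 100) {
  design_point(
    density = row$density,
    speed = speed_scenario(as.character(row$speed)),
    rest = rest_scenario(as.character(row$rest)),
    tracking = tracking_scenario(enabled = as.logical(row$tracking)),
    perception = perception_scenario(row$pd_max),
    facilitation = facilitation_scenario(row$tau),
    barrier = barrier_scenario(as.character(row$barrier),
                               arena_side = arena_side),
    design_index = row$design_index,
    allow_free_density = TRUE)
}

#' Design-size bookkeeping
#'
#' Total spawning days and simulated individuals implied by a design:
#' `spawning_days = n_runs * days` and
#' `individuals = runs_per_density * sum(densities)` for a 1-ha arena.
#' With the standard ten densities, 43,200 runs of 10 days (4,320 runs per
#' density) this reproduces 432,000 spawning days across 20,671,200
#' individuals.
#'
#' @param n_runs Total number of simulation runs.
#' @param days Days per run.
#' @param densities Density levels (adults/ha).
#' @param runs_per_density Runs at each density; defaults to
#'   `n_runs / length(densities)`, which must then be integral.
#' @return A list with `spawning_days` and `individuals`.
#' @export
design_totals <- function(n_runs, days, densities,
                          runs_per_density = NULL) {
  if (n_runs <= 0 || days <= 0 || any(densities <= 0))
    stop("counts and densities must be positive")
  if (is.null(runs_per_density)) {
    if (n_runs %% length(densities) != 0)
      stop("n_runs is not divisible by the number of densities")
    runs_per_density <- n_runs / length(densities)
  }
  if (runs_per_density <= 0) stop("runs_per_density must be positive")
  list(spawning_days = n_runs * days,
       individuals = runs_per_density * sum(densities))
}

#' Derive a reproducible per-run seed
#'
#' Platform-independent integer mixing of `(base_seed, design_index,
#' replicate_index)`: the index pair is folded into a single integer with
#' the Cantor pairing function (injective over pairs), the base seed is
#' scrambled through a small linear-congruential chain, and their sum is
#' passed through two bijective odd-multiplier rounds modulo 2^31.  All
#' arithmetic stays below 2^53 so the result is exact in doubles on every
#' platform.
#'
#' @param base_seed,design_index,replicate_index Non-negative integers.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_run_seed <- function(base_seed, design_index, replicate_index) {
  if (any(c(base_seed, design_index, replicate_index) < 0) ||
      any(c(base_seed, design_index, replicate_index) %% 1 != 0))
    stop("all seed components must be non-negative integers")
  m <- 2^31
  s <- design_index + replicate_index
  k <- s * (s + 1) / 2 + replicate_index   # Cantor pairing
  if (k >= m) stop("design/replicate indices too large for seed derivation")
  h <- base_seed %% m
  for (i in 1:3) h <- (h * 69069 + 362437) %% m
  v <- (h + k) %% m
  v <- (v * 3141601 + 271828183) %% m      # odd multiplier: bijection mod 2^31
  v <- (v * 69069 + 12345) %% m
  as.integer(v)   # v < 2^31 so this is exact (integer.max = 2^31 - 1)
}

#' @export
print.conch_design_point <- function(x, ...) {
  cat("Queen conch design point (index ", x$design_index, ")\n", sep = "")
  cat("  density      : ", x$density, " adults/ha\n", sep = "")
  cat("  speed        : ", x$speed$label, " (", x$speed$mean, " +/- ",
      x$speed$sd, " m/d, [", x$speed$lo, ", ", x$speed$hi, "])\n", sep = "")
  cat("  rest period  : ", x$rest$kind, "\n", sep = "")
  cat("  tracking     : ", if (x$tracking$enabled) "on" else "off", "\n",
      sep = "")
  cat("  perception   : U(0, ", x$perception$pd_max, ") m\n", sep = "")
  cat("  facilitation : tau = ", x$facilitation$tau, "\n", sep = "")
  cat("  barrier      : ", x$barrier$kind, "\n", sep = "")
  invisible(x)
}
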