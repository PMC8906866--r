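# population ids are 1..n so ids double as vector indices throughout
new_population <- function(n, barrier) {
  nf <- ceiling(n / 2)
  female <- c(rep(TRUE, nf), rep(FALSE, n - nf))
  # uniform placement, rejection-sampled to stay outside the barrier
  x <- numeric(n)
  y <- numeric(n)
  todo <- seq_len(n)
  side <- barrier$arena_side
  while (length(todo)) {
    x[todo] <- runif(length(todo), 0, side)
    y[todo] <- runif(length(todo), 0, side)
    if (barrier$kind == "none") break
    inside <- point_in_rect(x[todo], y[todo], barrier$rect)
    todo <- todo[inside]
  }
  list(id = seq_len(n), female = female, x = x, y = y,
       C = integer(n), receptive_after = rep(-Inf, n),
       n_matings = integer(n), first_mating_day = rep(NA_real_, n))
}

# nearest point on the rectangle boundary (any face); used as a safety net
# when wall reflection folds an endpoint into the barrier
nearest_rect_boundary <- function(x, y, rect) {
  dl <- x - rect[["xmin"]]; dr <- rect[["xmax"]] - x
  db <- y - rect[["ymin"]]; dt <- rect[["ymax"]] - y
  m <- pmin(dl, dr, db, dt)
  nx <- x; ny <- y
  nx[m == dl] <- rect[["xmin"]]
  nx[m == dr & m != dl] <- rect[["xmax"]]
  ny[m == db & m != dl & m != dr] <- rect[["ymin"]]
  ny[m == dt & m != dl & m != dr & m != db] <- rect[["ymax"]]
  list(x = nx, y = ny)
}

#' Run one simulation
#'
#' Simulates a single design point: adults placed uniformly at random in
#' the arena (outside any barrier), then for each day perception distances
#' are resampled, all agents move (truncated-normal speed, uniform
#' direction, optional scent-tracking taxis, barrier resolution, wall
#' reflection), encounters between daily paths are detected, matings are
#' resolved through receptivity and the facilitation gate, and spawning is
#' scheduled from first matings with the oogenesis delay.  Fully
#' deterministic given `seed`.
#'
#' @param dp A [design_point()].
#' @param config A [run_config()].
#' @param seed Integer seed for the run.
#' @param keep_events Keep the mating/spawn event ledgers in the result.
#' @return Object of class `conch_run`: list with `summary`
#'   ([summarize_run()] output), `events`, `spawns`, `pop`, `seed`.
#' @export
run_simulation <- function(dp, config = run_config(), seed = 1L,
                           keep_events = TRUE) {
  stopifnot(inherits(dp, "conch_design_point"),
            inherits(config, "conch_config"))
  side <- config$arena_side
  area_ha <- side^2 / 1e4
  n <- round(dp$density * area_ha)
  if (n < 2) stop("density x area gives fewer than 2 adults; no pair possible")
  barrier <- dp$barrier
  if (barrier$kind != "none" && barrier$arena_side != side)
    barrier <- barrier_scenario("one", arena_side = side,
                                orientation = barrier$orientation)
  set.seed(seed)
  pop <- new_population(n, barrier)
  sex <- ifelse(pop$female, "female", "male")
  track <- dp$tracking
  matings <- vector("list", config$days)
  for (day in seq_len(config$days)) {
    perception <- runif(n, 0, dp$perception$pd_max)
    speeds <- sample_speed(dp$speed, n)
    angles <- sample_direction(n)
    rad <- angles * pi / 180
    ex <- pop$x + speeds * cos(rad)
    ey <- pop$y + speeds * sin(rad)
    if (track$enabled) {
      if (track$same_sex_excluded) {
        f <- matrix(0, n, 2)
        fe <- pop$female
        f[fe, ] <- taxis_field(pop$x[!fe], pop$y[!fe],
                               pop$x[fe], pop$y[fe], track)
        f[!fe, ] <- taxis_field(pop$x[fe], pop$y[fe],
                                pop$x[!fe], pop$y[!fe], track)
      } else {
        f <- taxis_field(pop$x, pop$y, pop$x, pop$y, track)
      }
      ex <- ex + f[, 1]
      ey <- ey + f[, 2]
    }
    rb <- resolve_barrier_vec(pop$x, pop$y, ex, ey, barrier)
    ex <- fold_reflect(rb$x, side)
    ey <- fold_reflect(rb$y, side)
    if (barrier$kind != "none") {
      inb <- point_in_rect(ex, ey, barrier$rect)
      if (any(inb)) {
        fixed <- nearest_rect_boundary(ex[inb], ey[inb], barrier$rect)
        ex[inb] <- fixed$x
        ey[inb] <- fixed$y
      }
    }
    states <- data.frame(id = pop$id, sex = sex,
                         x0 = pop$x, y0 = pop$y, x1 = ex, y1 = ey,
                         perception = perception)
    enc <- detect_encounters(states, day)
    res <- process_day(pop, enc, dp$rest, dp$facilitation, day)
    pop <- res$pop
    matings[[day]] <- res$events
    pop$x <- ex
    pop$y <- ey
  }
  matings <- do.call(rbind, matings)
  mated_f <- which(pop$female & !is.na(pop$first_mating_day))
  spawns <- data.frame(female_id = integer(), day = numeric())
  if (length(mated_f)) {
    sl <- lapply(mated_f, function(i)
      schedule_spawns(pop$first_mating_day[i], config$spawn_delay,
                      config$days))
    k <- lengths(sl)
    spawns <- data.frame(female_id = rep(pop$id[mated_f], k),
                         day = unlist(sl, use.names = FALSE))
  }
  events <- list(matings = matings, spawns = spawns)
  summ <- summarize_run(events, n, config$days, config$mating_metric)
  structure(list(summary = summ,
                 events = if (keep_events) matings else NULL,
                 spawns = if (keep_events) spawns else NULL,
                 pop = pop, seed = seed, density = dp$density,
                 days = config$days),
            class = "conch_run")
}

#' @export
print.conch_run <- function(x, ...) {
  cat(sprintf(
    "conch_run (density %g, seed %d): %.1f%% mating, %.1f%% spawning\n",
    x$density, x$seed, x$summary$pct_mating, x$summary$pct_spawning))
  invisible(x)
}

# mean and t-based 95% confidence interval
t_ci <- function(v, level = 0.95) {
  n <- length(v)
  m <- mean(v)
  if (n < 2) return(c(mean = m, lo = m, hi = m))
  se <- sd(v) / sqrt(n)
  q <- qt(1 - (1 - level) / 2, df = n - 1)
  c(mean = m, lo = m - q * se, hi = m + q * se)
}

#' Run all replicates of one design point
#'
#' Replicate seeds are derived from the config base seed, the design index
#' and the replicate index, so replicate r of design point d is identical
#' whether runs execute serially or in any other order.  Percent mating
#' and spawning are aggregated as the replicate mean with a Student-t 95%
#' confidence interval (df = replicates - 1).
#'
#' @param dp A [design_point()].
#' @param config A [run_config()].
#' @param replicates Override the config replicate count.
#' @return Object of class `conch_replicates`: per-replicate values plus
#'   mean and 95% CI of percent mating and spawning.
#' @export
run_replicates <- function(dp, config = run_config(), replicates = NULL) {
  reps <- if (is.null(replicates)) config$replicates else replicates
  pm <- numeric(reps)
  ps <- numeric(reps)
  seeds <- integer(reps)
  for (r in seq_len(reps)) {
    seeds[r] <- derive_run_seed(config$base_seed, dp$design_index, r)
    run <- run_simulation(dp, config, seed = seeds[r], keep_events = FALSE)
    pm[r] <- run$summary$pct_mating
    ps[r] <- run$summary$pct_spawning
  }
  cm <- t_ci(pm)
  cs <- t_ci(ps)
  structure(list(design_index = dp$design_index, density = dp$density,
                 pct_mating = pm, pct_spawning = ps, seeds = seeds,
                 mean_pct_mating = cm[["mean"]], ci_lo = cm[["lo"]],
                 ci_hi = cm[["hi"]],
                 mean_pct_spawning = cs[["mean"]], sp_ci_lo = cs[["lo"]],
                 sp_ci_hi = cs[["hi"]], replicates = reps),
            class = "conch_replicates")
}

#' @export
print.conch_replicates <- function(x, ...) {
  cat(sprintf(
    "design %d (density %g, %d reps): mating %.1f%% [%.1f, %.1f], spawning %.1f%% [%.1f, %.1f]\n",
    x$design_index, x$density, x$replicates,
    x$mean_pct_mating, x$ci_lo, x$ci_hi,
    x$mean_pct_spawning, x$sp_ci_lo, x$sp_ci_hi))
  invisible(x)
}

#' Run a factorial design
#'
#' Executes [run_replicates()] for every row of a design grid and returns
#' one results row per design point.  When `file` is given, results are
#' appended after each design point and a rerun resumes, skipping design
#' indices already present in the file.
#'
#' @param grid Data.frame from [build_design_grid()].
#' @param config A [run_config()].
#' @param file Optional CSV path for incremental/resumable output.
#' @param verbose Emit one progress line per design point to stderr.
#' @return Data.frame with columns `design_index`, the factor levels, and
#'   mean/CI percent mating and spawning.
#' @export
run_design <- function(grid, config = run_config(), file = NULL,
                       verbose = FALSE) {
  if (nrow(grid) == 0L) stop("empty design grid")
  done <- NULL
  if (!is.null(file) && file.exists(file)) {
    done <- read.csv(file, stringsAsFactors = FALSE)
    if (anyDuplicated(done$design_index))
      stop("duplicate design_index in resume file ", file)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, , drop = FALSE]
    if (!is.null(done) && gi$design_index %in% done$design_index) {
      rows[[i]] <- done[done$design_index == gi$design_index, , drop = FALSE]
      next
    }
    dp <- design_point_from_row(gi, arena_side = config$arena_side)
    t0 <- proc.time()[["elapsed"]]
    rs <- run_replicates(dp, config)
    row <- data.frame(design_index = gi$design_index, density = gi$density,
                      speed = gi$speed, rest = gi$rest,
                      tracking = gi$tracking, pd_max = gi$pd_max,
                      tau = gi$tau, barrier = gi$barrier,
                      mean_pct_mating = rs$mean_pct_mating,
                      ci_lo = rs$ci_lo, ci_hi = rs$ci_hi,
                      mean_pct_spawning = rs$mean_pct_spawning,
                      sp_ci_lo = rs$sp_ci_lo, sp_ci_hi = rs$sp_ci_hi,
                      replicates = rs$replicates,
                      stringsAsFactors = FALSE)
    rows[[i]] <- row
    if (verbose)
      message(sprintf("design %d: density %g, mating %.1f%% (%.1fs)",
                      gi$design_index, gi$density, rs$mean_pct_mating,
                      proc.time()[["elapsed"]] - t0))
    if (!is.null(file)) {
      out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      write_results(out, file)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot mean percent-mating curves from design results
#'
#' Base-graphics curves of mean percent mating (or spawning) against log10
#' density, one line per level of `by`, other factors held at the value
#' most common in `results`.
#'
#' @param results Data.frame from [run_design()].
#' @param by Factor column to split curves by.
#' @param what `"mating"` or `"spawning"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_design_curves <- function(results, by = "speed",
                               what = c("mating", "spawning"), ...) {
  what <- match.arg(what)
  ycol <- if (what == "mating") "mean_pct_mating" else "mean_pct_spawning"
  levs <- unique(results[[by]])
  dens <- sort(unique(results$density))
  ym <- sapply(levs, function(l) {
    sub <- results[results[[by]] == l, , drop = FALSE]
    sapply(dens, function(d) mean(sub[[ycol]][sub$density == d]))
  })
  matplot(log10(dens), ym, type = "b", pch = 16, lty = 1,
          xlab = "log10 density (adults/ha)",
          ylab = paste("mean %", what), ...)
  legend("topleft", legend = paste(by, "=", levs), col = seq_along(levs),
         lty = 1, pch = 16, bty = "n")
  invisible(ym)
}
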