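# Independent oracles used across the suite.  Each is deliberately written
# from first principles (quadrature, dense sampling, double loops) rather
# than by calling the implementation it checks.

# truncated-normal moments by numerical integration
oracle_truncnorm_mean <- function(mean, sd, lo, hi) {
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  integrate(function(x) x * dnorm(x, mean, sd) / z, lo, hi,
            rel.tol = 1e-10)$value
}

oracle_truncnorm_cdf <- function(q, mean, sd, lo, hi) {
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  (pnorm(pmin(pmax(q, lo), hi), mean, sd) - pnorm(lo, mean, sd)) / z
}

# distance from a point to a closed segment (closed form)
oracle_point_seg_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((px - x0) * dx + (py - y0) * dy) / L2, 0), 1)
  sqrt((x0 + t * dx - px)^2 + (y0 + t * dy - py)^2)
}

# min distance between segments by densely sampling one segment and taking
# exact point-to-segment distances to the other (error <= half the sample
# spacing)
oracle_seg_dist <- function(a, b, n = 2001) {
  t <- seq(0, 1, length.out = n)
  px <- a$start[1] + t * (a$end[1] - a$start[1])
  py <- a$start[2] + t * (a$end[2] - a$start[2])
  min(oracle_point_seg_dist(px, py, b$start[1], b$start[2],
                            b$end[1], b$end[2]))
}

# exact pairwise attraction by double loop in R (same force law:
# strength / max(d, dmin) toward each neighbour within max_dist)
oracle_taxis <- function(fx, fy, ox, oy, strength, max_dist, dmin) {
  acc <- c(0, 0)
  for (j in seq_along(ox)) {
    dx <- ox[j] - fx
    dy <- oy[j] - fy
    d <- sqrt(dx^2 + dy^2)
    if (d < 1e-12 || d > max_dist) next
    w <- strength / max(d, dmin) / d
    acc <- acc + c(dx, dy) * w
  }
  acc
}

# iterated mirror reflection into [0, L]
oracle_fold <- function(v, L) {
  while (v < 0 || v > L) {
    if (v < 0) v <- -v
    if (v > L) v <- 2 * L - v
  }
  v
}

# closest boundary point of an axis-aligned rectangle on the start's side
# (vertical wall: side defined by x relative to the centre line), by dense
# boundary sampling
oracle_barrier_relocation <- function(start, end, rect, n = 20001) {
  xs <- c(seq(rect[["xmin"]], rect[["xmax"]], length.out = n),
          seq(rect[["xmin"]], rect[["xmax"]], length.out = n),
          rep(rect[["xmin"]], n), rep(rect[["xmax"]], n))
  ys <- c(rep(rect[["ymin"]], n), rep(rect[["ymax"]], n),
          seq(rect[["ymin"]], rect[["ymax"]], length.out = n),
          seq(rect[["ymin"]], rect[["ymax"]], length.out = n))
  cx <- (rect[["xmin"]] + rect[["xmax"]]) / 2
  side <- if (start[1] < cx) xs <= cx else xs >= cx
  xs <- xs[side]
  ys <- ys[side]
  d2 <- (xs - end[1])^2 + (ys - end[2])^2
  i <- which.min(d2)
  c(xs[i], ys[i])
}

# all-pairs encounter detection in R using the exported segment distance
oracle_encounters <- function(states) {
  m <- states[states$sex == "male", , drop = FALSE]
  f <- states[states$sex == "female", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(f))) {
      a <- list(start = c(m$x0[i], m$y0[i]), end = c(m$x1[i], m$y1[i]))
      b <- list(start = c(f$x0[j], f$y0[j]), end = c(f$x1[j], f$y1[j]))
      if (segment_min_distance(a, b) <= max(m$perception[i], f$perception[j]))
        out[[length(out) + 1L]] <- c(m$id[i], f$id[j])
    }
  }
  if (!length(out))
    return(data.frame(male_id = integer(), female_id = integer()))
  d <- as.data.frame(do.call(rbind, out))
  names(d) <- c("male_id", "female_id")
  d[order(d$male_id, d$female_id), , drop = FALSE]
}

# random daily-path states table for encounter tests
random_states <- function(n, side = 100, pd_max = 3, speed_max = 10) {
  x0 <- runif(n, 0, side)
  y0 <- runif(n, 0, side)
  ang <- runif(n, 0, 2 * pi)
  sp <- runif(n, 0, speed_max)
  data.frame(id = seq_len(n),
             sex = ifelse(seq_len(n) %% 2 == 0, "male", "female"),
             x0 = x0, y0 = y0,
             x1 = pmin(pmax(x0 + sp * cos(ang), 0), side),
             y1 = pmin(pmax(y0 + sp * sin(ang), 0), side),
             perception = runif(n, 0, pd_max),
             stringsAsFactors = FALSE)
}

# small population object matching the engine's internal layout
make_pop <- function(n, n_female = ceiling(n / 2)) {
  list(id = seq_len(n),
       female = c(rep(TRUE, n_female), rep(FALSE, n - n_female)),
       x = rep(0, n), y = rep(0, n),
       C = integer(n), receptive_after = rep(-Inf, n),
       n_matings = integer(n), first_mating_day = rep(NA_real_, n))
}

lowest_point <- function(density, tracking = FALSE, design_index = 1L, ...) {
  design_point(density,
               speed = speed_scenario("low"),
               rest = rest_scenario("zero"),
               tracking = tracking_scenario(tracking),
               perception = perception_scenario(0.5),
               facilitation = facilitation_scenario(0),
               barrier = barrier_scenario("none"),
               design_index = design_index, ...)
}

mean_pct_mating <- function(dp, reps, base_seed = 1L, config = run_config()) {
  v <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- derive_run_seed(base_seed, dp$design_index, r)
    v[r] <- run_simulation(dp, config, seed = s,
                           keep_events = FALSE)$summary$pct_mating
  }
  v
}
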