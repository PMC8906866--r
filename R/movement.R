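#' Truncated-normal sampler
#'
#' Inverse-CDF sampling of a normal(mean, sd) conditioned on `[lo, hi]`.
#' Degenerate `sd = 0` returns `mean` exactly.  Draws come from R's RNG
#' stream (one uniform per variate), so sequences are reproducible under
#' `set.seed()`.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of length `n`, all values in `[lo, hi]`.
#' @export
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (lo > hi) stop("truncation bounds: lo > hi")
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop("degenerate distribution: mean outside truncation bounds")
    return(rep(mean, n))
  }
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  x <- qnorm(runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Sample daily movement speeds
#'
#' @param speed A [speed_scenario()] object.
#' @param n Number of draws.
#' @return Speeds in m/day, each within the scenario's truncation bounds.
#' @export
sample_speed <- function(speed, n = 1) {
  stopifnot(inherits(speed, "conch_speed"))
  rtruncnorm(n, speed$mean, speed$sd, speed$lo, speed$hi)
}

#' Sample movement directions
#'
#' Uniform on the circle, in degrees.
#'
#' @param n Number of draws.
#' @return Angles in `[0, 360)` degrees.
#' @export
sample_direction <- function(n = 1) {
  runif(n, 0, 360) %% 360
}

#' Draw one interbreeding rest duration
#'
#' @param rest A [rest_scenario()] object.
#' @return Rest duration in days (`0` for the `"zero"` kind, which consumes
#'   no random numbers).
#' @export
sample_rest <- function(rest) {
  stopifnot(inherits(rest, "conch_rest"))
  switch(rest$kind,
    zero = 0,
    uniform = runif(1, rest$params$lo, rest$params$hi),
    truncnorm = rtruncnorm(1, rest$params$mean, rest$params$sd,
                           rest$params$lo, rest$params$hi))
}

# attraction field at target points from source points; deterministic
taxis_field <- function(sx, sy, tx, ty, tracking,
                        method = c("auto", "exact", "barnes_hut")) {
  method <- match.arg(method)
  if (!tracking$enabled || length(sx) == 0L)
    return(matrix(0, length(tx), 2))
  if (method == "auto")
    method <- if (length(sx) >= 200L) "barnes_hut" else "exact"
  f <- if (method == "exact") {
    taxis_exact_cpp(sx, sy, tx, ty, tracking$strength,
                    tracking$max_taxis_distance, tracking$distance_min)
  } else {
    taxis_bh_cpp(sx, sy, tx, ty, tracking$strength,
                 tracking$max_taxis_distance, tracking$distance_min,
                 tracking$theta)
  }
  # cap the net displacement at the daily taxis range
  nrm <- sqrt(f[, 1]^2 + f[, 2]^2)
  over <- nrm > tracking$max_taxis_distance
  if (any(over)) {
    sc <- tracking$max_taxis_distance / nrm[over]
    f[over, 1] <- f[over, 1] * sc
    f[over, 2] <- f[over, 2] * sc
  }
  f
}

#' Scent-tracking taxis displacement for one individual
#'
#' Sum of pairwise attraction contributions from conspecifics within the
#' tracking influence radius; each neighbour at distance d contributes a
#' vector of magnitude `strength / max(d, distance_min)` pointing toward
#' it.  Neighbours beyond the influence radius contribute nothing;
#' coincident neighbours (d = 0) are skipped.  The summed displacement is
#' capped at `max_taxis_distance`.  With `method = "barnes_hut"` distant
#' groups are aggregated to their centre of mass (opening criterion
#' `theta`); the result approximates the exact pairwise sum.
#'
#' @param focal_position Numeric `c(x, y)` of the focal individual, m.
#' @param other_positions Two-column matrix of conspecific positions.
#' @param tracking A [tracking_scenario()] object.
#' @param method `"exact"` pairwise sum, `"barnes_hut"`, or `"auto"`.
#' @return Numeric `c(dx, dy)` displacement in m; `c(0, 0)` when tracking
#'   is disabled.
#' @export
taxis_displacement <- function(focal_position, other_positions, tracking,
                               method = c("auto", "exact", "barnes_hut")) {
  stopifnot(inherits(tracking, "conch_tracking"))
  if (!tracking$enabled) return(c(0, 0))
  other_positions <- matrix(other_positions, ncol = 2)
  f <- taxis_field(other_positions[, 1], other_positions[, 2],
                   focal_position[1], focal_position[2],
                   tracking, method = match.arg(method))
  c(f[1, 1], f[1, 2])
}

#' Propose a daily path segment (pre-constraint)
#'
#' `end = position + speed * (cos angle, sin angle) + taxis`.
#'
#' @param position `c(x, y)` start position, m.
#' @param speed Daily speed, m.
#' @param angle Direction in degrees.
#' @param taxis `c(dx, dy)` taxis displacement (default none).
#' @return A path segment: `list(start, end)`.
#' @export
propose_step <- function(position, speed, angle, taxis = c(0, 0)) {
  if (speed < 0) stop("speed must be >= 0")
  rad <- angle * pi / 180
  list(start = position,
       end = position + speed * c(cos(rad), sin(rad)) + taxis)
}

# segment/axis-aligned-rectangle intersection, vectorised (slab method).
# x0,y0 -> x1,y1 are segments; rect = c(xmin, xmax, ymin, ymax).
seg_hits_rect <- function(x0, y0, x1, y1, rect) {
  dx <- x1 - x0
  dy <- y1 - y0
  dx <- ifelse(dx == 0, 1e-300, dx)
  dy <- ifelse(dy == 0, 1e-300, dy)
  tx1 <- (rect[["xmin"]] - x0) / dx
  tx2 <- (rect[["xmax"]] - x0) / dx
  ty1 <- (rect[["ymin"]] - y0) / dy
  ty2 <- (rect[["ymax"]] - y0) / dy
  tmin <- pmax(pmin(tx1, tx2), pmin(ty1, ty2), 0)
  tmax <- pmin(pmax(tx1, tx2), pmax(ty1, ty2), 1)
  tmin <= tmax
}

point_in_rect <- function(x, y, rect, strict = TRUE) {
  if (strict) {
    x > rect[["xmin"]] & x < rect[["xmax"]] &
      y > rect[["ymin"]] & y < rect[["ymax"]]
  } else {
    x >= rect[["xmin"]] & x <= rect[["xmax"]] &
      y >= rect[["ymin"]] & y <= rect[["ymax"]]
  }
}

# closest point on the start's side of the rectangle boundary to (qx, qy).
# Side is defined along the crossing (short) axis.  Vectorised.
closest_exterior_on_side <- function(sx, sy, qx, qy, rect, orientation) {
  if (orientation == "horizontal") {
    # swap coordinates so the wall's long axis is y
    res <- closest_exterior_on_side(sy, sx, qy, qx,
                                    c(xmin = rect[["ymin"]],
                                      xmax = rect[["ymax"]],
                                      ymin = rect[["xmin"]],
                                      ymax = rect[["xmax"]]),
                                    "vertical")
    return(list(x = res$y, y = res$x))
  }
  cx <- (rect[["xmin"]] + rect[["xmax"]]) / 2
  left <- sx < cx
  xface <- ifelse(left, rect[["xmin"]], rect[["xmax"]])
  # candidate 1: the long face on the start's side
  c1x <- xface
  c1y <- pmin(pmax(qy, rect[["ymin"]]), rect[["ymax"]])
  # candidates 2/3: the start-side halves of the short caps
  xlo <- ifelse(left, rect[["xmin"]], cx)
  xhi <- ifelse(left, cx, rect[["xmax"]])
  c2x <- pmin(pmax(qx, xlo), xhi)
  c2y <- rect[["ymin"]]
  c3x <- c2x
  c3y <- rect[["ymax"]]
  d1 <- (qx - c1x)^2 + (qy - c1y)^2
  d2 <- (qx - c2x)^2 + (qy - c2y)^2
  d3 <- (qx - c3x)^2 + (qy - c3y)^2
  n <- length(qx)
  bx <- rep_len(c1x, n)
  by <- rep_len(c1y, n)
  b2 <- d2 < d1 & d2 <= d3
  bx[b2] <- rep_len(c2x, n)[b2]
  by[b2] <- c2y
  b3 <- d3 < d1 & d3 < d2
  bx[b3] <- rep_len(c3x, n)[b3]
  by[b3] <- c3y
  list(x = bx, y = by)
}

#' Resolve a path segment against a movement barrier
#'
#' If the segment neither crosses nor ends inside the barrier it is
#' returned unchanged.  Otherwise the intended end is replaced by the
#' closest point on the barrier exterior lying on the start's side, so the
#' barrier both relocates endpoints that land inside it and blocks
#' pass-through.
#'
#' @param segment `list(start, end)` path segment.
#' @param barrier A [barrier_scenario()] object.
#' @return A path segment whose end is never strictly inside the barrier.
#' @export
resolve_barrier <- function(segment, barrier) {
  stopifnot(inherits(barrier, "conch_barrier"))
  if (barrier$kind == "none") return(segment)
  rect <- barrier$rect
  s <- segment$start
  e <- segment$end
  if (point_in_rect(s[1], s[2], rect))
    stop("segment starts inside the barrier (upstream invariant violated)")
  hit <- seg_hits_rect(s[1], s[2], e[1], e[2], rect)
  if (!hit) return(segment)
  cp <- closest_exterior_on_side(s[1], s[2], e[1], e[2], rect,
                                 barrier$orientation)
  list(start = s, end = c(cp$x, cp$y))
}

# vectorised barrier resolution used by the engine
resolve_barrier_vec <- function(x0, y0, x1, y1, barrier) {
  if (barrier$kind == "none") return(list(x = x1, y = y1))
  rect <- barrier$rect
  hit <- seg_hits_rect(x0, y0, x1, y1, rect)
  if (any(hit)) {
    cp <- closest_exterior_on_side(x0[hit], y0[hit], x1[hit], y1[hit],
                                   rect, barrier$orientation)
    x1[hit] <- cp$x
    y1[hit] <- cp$y
  }
  list(x = x1, y = y1)
}

# fold a coordinate into [0, L] by mirror reflection
fold_reflect <- function(v, L) {
  r <- v %% (2 * L)
  ifelse(r > L, 2 * L - r, r)
}

#' Reflect a path segment end at the arena walls
#'
#' Coordinates outside `[0, arena_side]` are folded back by mirror
#' reflection at each crossed edge (path length along the wall-bounced
#' trajectory is preserved; the stored segment keeps the start and the
#' folded end).
#'
#' @param segment `list(start, end)` with start inside the arena.
#' @param arena_side Arena side length, m.
#' @return Segment with end inside `[0, arena_side]^2`.
#' @export
reflect_at_bounds <- function(segment, arena_side) {
  e <- segment$end
  list(start = segment$start,
       end = c(fold_reflect(e[1], arena_side),
               fold_reflect(e[2], arena_side)))
}
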