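#' Minimum distance between two daily path segments
#'
#' Exact minimum Euclidean distance between two closed 2-D segments,
#' computed from the clamped closest-point parametrisation.  Symmetric;
#' zero exactly when the segments touch or cross.
#'
#' @param a,b Path segments, each `list(start = c(x, y), end = c(x, y))`.
#' @return Distance in m.
#' @export
segment_min_distance <- function(a, b) {
  p0 <- as.numeric(a$start); p1 <- as.numeric(a$end)
  q0 <- as.numeric(b$start); q1 <- as.numeric(b$end)
  d1 <- p1 - p0
  d2 <- q1 - q0
  r <- p0 - q0
  A <- sum(d1 * d1)
  E <- sum(d2 * d2)
  f <- sum(d2 * r)
  clamp <- function(v) min(max(v, 0), 1)
  eps <- 1e-14
  if (A <= eps && E <= eps) {
    s <- 0; t <- 0
  } else if (A <= eps) {
    s <- 0; t <- clamp(f / E)
  } else {
    cc <- sum(d1 * r)
    if (E <= eps) {
      t <- 0; s <- clamp(-cc / A)
    } else {
      b2 <- sum(d1 * d2)
      denom <- A * E - b2 * b2
      s <- if (denom > eps) clamp((b2 * f - cc * E) / denom) else 0
      t <- (b2 * s + f) / E
      if (t < 0) {
        t <- 0; s <- clamp(-cc / A)
      } else if (t > 1) {
        t <- 1; s <- clamp((b2 - cc) / A)
      }
    }
  }
  sqrt(sum((p0 + s * d1 - (q0 + t * d2))^2))
}

#' Detect male-female path encounters for one day
#'
#' An encounter is an opposite-sex pair whose daily paths pass within the
#' larger of the two individuals' perception distances (one individual
#' perceiving suffices to close the gap).  The accelerated C++ scan is
#' exact: it must (and does, see the test suite) return the same set as an
#' all-pairs brute force.
#'
#' @param states A data.frame with one row per individual and columns
#'   `id`, `sex` (`"male"`/`"female"`), `x0`, `y0`, `x1`, `y1` (today's
#'   path endpoints, m) and `perception` (today's perception distance, m).
#' @param day Optional day number attached to the result.
#' @return data.frame with columns `male_id`, `female_id`, `distance`,
#'   ordered by `(male_id, female_id)`.
#' @export
detect_encounters <- function(states, day = NA_integer_) {
  need <- c("id", "sex", "x0", "y0", "x1", "y1", "perception")
  if (!all(need %in% names(states)))
    stop("states must have columns: ", paste(need, collapse = ", "))
  im <- states$sex == "male"
  fe <- states$sex == "female"
  m <- states[im, , drop = FALSE]
  f <- states[fe, , drop = FALSE]
  if (nrow(m) == 0L || nrow(f) == 0L) {
    return(data.frame(male_id = integer(), female_id = integer(),
                      distance = numeric()))
  }
  hits <- encounter_pairs_cpp(m$x0, m$y0, m$x1, m$y1, m$perception,
                              f$x0, f$y0, f$x1, f$y1, f$perception)
  out <- data.frame(male_id = m$id[hits[, 1]],
                    female_id = f$id[hits[, 2]],
                    distance = hits[, 3])
  out <- out[order(out$male_id, out$female_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "day") <- day
  out
}

#' Sexual-facilitation mating gate
#'
#' With facilitation threshold `tau`, a mating attempt by a female with
#' cumulative contact count `C` succeeds when `u < min(1, C / tau)`;
#' `tau = 0` means no facilitation is required and the gate always passes.
#'
#' @param C Cumulative opposite-sex contact count(s), non-negative.
#' @param tau Facilitation threshold (scalar).
#' @param u Uniform draw(s) in `[0, 1)`.
#' @return Logical vector: `TRUE` = pass.
#' @export
facilitation_gate <- function(C, tau, u) {
  if (tau < 0) stop("tau must be >= 0")
  if (any(C < 0)) stop("contact counts must be >= 0")
  if (tau == 0) return(rep(TRUE, max(length(C), length(u))))
  u < pmin(1, C / tau)
}

#' Process one day's encounters into matings
#'
#' Every encounter increments both members' contact counts.  A mating is
#' recorded for an encounter when the female is receptive
#' (`day >= receptive_after`), has not yet mated today, and the
#' facilitation gate passes (evaluated with the contact count including the
#' current encounter).  After a mating the female becomes unreceptive until
#' `day + 1 + rest draw`; males are unrestricted.  Encounters are processed
#' in an order shuffled once with the run RNG to avoid id-order bias, and
#' one gate uniform is drawn per encounter regardless of `tau` so runs with
#' different thresholds consume identical random-number streams.
#'
#' @param pop A population object as created inside [run_simulation()]
#'   (list with vectors `id`, `female`, `C`, `receptive_after`,
#'   `n_matings`, `first_mating_day`).
#' @param encounters data.frame from [detect_encounters()].
#' @param rest A [rest_scenario()].
#' @param facilitation A [facilitation_scenario()].
#' @param day Current day number (1-based).
#' @return `list(pop, events)` where `events` is a data.frame with one row
#'   per mating: `day`, `male_id`, `female_id`, `rest_draw`.
#' @export
process_day <- function(pop, encounters, rest, facilitation, day) {
  tau <- facilitation$tau
  ne <- nrow(encounters)
  ev_m <- integer(0); ev_f <- integer(0); ev_r <- numeric(0)
  if (ne > 0L) {
    if (any(pop$female[encounters$male_id]) ||
        any(!pop$female[encounters$female_id]))
      stop("encounter pair is not male x female")
    ord <- sample.int(ne)
    u <- runif(ne)
    mi <- encounters$male_id[ord]
    fi <- encounters$female_id[ord]
    C <- pop$C
    recv <- pop$receptive_after
    mated_today <- rep(FALSE, length(pop$id))
    for (k in seq_len(ne)) {
      m <- mi[k]; f <- fi[k]
      C[f] <- C[f] + 1L
      C[m] <- C[m] + 1L
      if (day >= recv[f] && !mated_today[f] &&
          (tau == 0 || u[k] < min(1, C[f] / tau))) {
        mated_today[f] <- TRUE
        rd <- sample_rest(rest)
        recv[f] <- day + 1 + rd
        ev_m <- c(ev_m, m); ev_f <- c(ev_f, f); ev_r <- c(ev_r, rd)
      }
    }
    pop$C <- C
    pop$receptive_after <- recv
    if (length(ev_f)) {
      pop$n_matings[ev_f] <- pop$n_matings[ev_f] + 1L
      tab <- table(factor(ev_m, levels = pop$id))
      pop$n_matings <- pop$n_matings + as.integer(tab)
      newly <- ev_f[is.na(pop$first_mating_day[ev_f])]
      pop$first_mating_day[newly] <- day
    }
  }
  list(pop = pop,
       events = data.frame(day = rep(day, length(ev_f)),
                           male_id = ev_m, female_id = ev_f,
                           rest_draw = ev_r))
}

#' Schedule oogenesis-delayed spawning events
#'
#' The first spawn follows the female's first mating after one draw from
#' the spawn-delay distribution; each subsequent spawn follows the previous
#' one after a fresh draw.  No re-mating is required (females store sperm).
#' Spawns after the end of the season are discarded.  A drawn delay of
#' exactly zero produces a spawn coincident with the previous event and
#' ends the schedule (two egg masses cannot be deposited at the same
#' instant).
#'
#' @param first_mating_day Day of the female's first mating; `NA` is an
#'   error (unmated females do not spawn).
#' @param spawn_delay List with truncated-normal parameters `mean`, `sd`,
#'   `lo`, `hi` (days).
#' @param season_days Length of the season in days.
#' @return Numeric vector of spawn days (possibly empty).
#' @export
schedule_spawns <- function(first_mating_day, spawn_delay, season_days) {
  if (is.na(first_mating_day))
    stop("schedule_spawns called for an unmated female")
  out <- numeric(0)
  t <- first_mating_day
  repeat {
    d <- rtruncnorm(1, spawn_delay$mean, spawn_delay$sd,
                    spawn_delay$lo, spawn_delay$hi)
    t <- t + d
    if (t > season_days) break
    out <- c(out, t)
    if (d == 0) break
  }
  out
}

#' Summarise a completed run
#'
#' Cumulative mode: percent mating is 100 x (adults with at least one
#' mating event) / n_adults, percent spawning is 100 x (females with at
#' least one spawn) / n_adults (all-adults denominator).  Daily-mean mode
#' replaces percent mating with the mean over days of the percent of
#' adults mating that day.
#'
#' @param events List with components `matings` (data.frame `day`,
#'   `male_id`, `female_id`) and `spawns` (data.frame `female_id`, `day`).
#' @param n_adults Number of adults in the run.
#' @param days Number of simulated days.
#' @param metric `"cumulative"` or `"daily_mean"`.
#' @return Object of class `conch_summary`: list with `pct_mating`,
#'   `pct_spawning`, `n_matings`, `n_spawns`, `n_adults`, `metric`.
#' @export
summarize_run <- function(events, n_adults, days,
                          metric = c("cumulative", "daily_mean")) {
  metric <- match.arg(metric)
  if (n_adults <= 0) stop("n_adults must be positive")
  mt <- events$matings
  sp <- events$spawns
  if (metric == "cumulative") {
    mated <- unique(c(mt$male_id, mt$female_id))
    pct_mating <- 100 * length(mated) / n_adults
  } else {
    per_day <- vapply(seq_len(days), function(d) {
      rows <- mt$day == d
      length(unique(c(mt$male_id[rows], mt$female_id[rows])))
    }, 1L)
    pct_mating <- mean(100 * per_day / n_adults)
  }
  pct_spawning <- 100 * length(unique(sp$female_id)) / n_adults
  structure(list(pct_mating = pct_mating, pct_spawning = pct_spawning,
                 n_matings = nrow(mt), n_spawns = nrow(sp),
                 n_adults = n_adults, metric = metric),
            class = "conch_summary")
}

#' @export
print.conch_summary <- function(x, ...) {
  cat(sprintf("conch run: %.1f%% mating, %.1f%% spawning (%d adults, %s)\n",
              x$pct_mating, x$pct_spawning, x$n_adults, x$metric))
  invisible(x)
}
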