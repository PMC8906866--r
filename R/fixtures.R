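#' Specification for synthetic density-reproduction observations
#'
#' Generates survey-style observations from a known dose-response curve
#' plus Gaussian noise, standing in for field datasets that are not
#' publicly deposited.  The `"bahamas"` preset uses a steep log-logistic
#' mating curve with asymptote 10.16% and ED50 64.35 adults/ha; the
#' `"florida"` preset uses asymptote 10.43% and ED50 204.83 adults/ha.
#' Paired percent-spawning values, when requested, follow an asymptotic
#' curve of the realised percent mating (plateau 10.22, rate 0.19).  All
#' generated data are synthetic.
#'
#' @param source `"bahamas"`, `"florida"`, or `"custom"`.
#' @param b,d,e Log-logistic mating-curve parameters (slope, asymptote,
#'   ED50); defaults follow the chosen preset.
#' @param densities Densities to sample at, adults/ha.
#' @param noise_sd Gaussian noise SD, percentage points.
#' @param records_per_density Observations generated per density.
#' @param zero_inflation Probability that a record at a density below
#'   `zero_inflation_below` is recorded as zero mating (surveys often find
#'   no activity at sparse sites).
#' @param zero_inflation_below Density cutoff for zero inflation.
#' @param spawning Also generate paired percent spawning.
#' @param spawn_d,spawn_e Asymptotic spawning-curve parameters.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Object of class `conch_fixture_spec`.
#' @export
fixture_spec <- function(source = c("bahamas", "florida", "custom"),
                         b = NULL, d = NULL, e = NULL,
                         densities = conch_densities(),
                         noise_sd = 2, records_per_density = 5,
                         zero_inflation = 0.1, zero_inflation_below = 100,
                         spawning = TRUE, spawn_d = 10.22, spawn_e = 0.19,
                         seed = 1L) {
  source <- match.arg(source)
  presets <- list(bahamas = c(b = -56.18, d = 10.16, e = 64.35),
                  florida = c(b = -71.04, d = 10.43, e = 204.83))
  if (source != "custom") {
    p <- presets[[source]]
    if (is.null(b)) b <- p[["b"]]
    if (is.null(d)) d <- p[["d"]]
    if (is.null(e)) e <- p[["e"]]
  }
  if (is.null(b) || is.null(d) || is.null(e))
    stop("custom fixtures require b, d and e")
  stopifnot(d >= 0, e > 0, noise_sd >= 0, records_per_density >= 1,
            zero_inflation >= 0, zero_inflation <= 1, all(densities > 0))
  structure(list(source = source, b = b, d = d, e = e,
                 densities = densities, noise_sd = noise_sd,
                 records_per_density = as.integer(records_per_density),
                 zero_inflation = zero_inflation,
                 zero_inflation_below = zero_inflation_below,
                 spawning = isTRUE(spawning),
                 spawn_d = spawn_d, spawn_e = spawn_e,
                 seed = as.integer(seed)),
            class = "conch_fixture_spec")
}

#' Generate synthetic empirical-style observations
#'
#' Percent mating is the spec's log-logistic curve evaluated at each
#' density plus Gaussian noise, clipped to `[0, 100]`; optionally a record
#' is zero-inflated at low density.  Percent spawning (when requested)
#' follows the asymptotic curve of the realised percent mating plus the
#' same noise, clipped.  Deterministic for a given spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return data.frame with columns `source`, `density_per_ha`,
#'   `pct_mating`, `pct_spawning` (the latter `NA` when `spawning` is
#'   off).
#' @export
generate_observations <- function(spec) {
  stopifnot(inherits(spec, "conch_fixture_spec"))
  set.seed(spec$seed)
  dens <- rep(spec$densities, each = spec$records_per_density)
  n <- length(dens)
  mu <- ll3(dens, spec$b, spec$d, spec$e)
  y <- pmin(pmax(mu + rnorm(n, 0, spec$noise_sd), 0), 100)
  zi <- runif(n) < spec$zero_inflation & dens < spec$zero_inflation_below
  y[zi] <- 0
  sp <- rep(NA_real_, n)
  if (spec$spawning) {
    mu_s <- asy2(y, spec$spawn_d, spec$spawn_e)
    sp <- pmin(pmax(mu_s + rnorm(n, 0, spec$noise_sd), 0), 100)
  }
  data.frame(source = rep(paste0(spec$source, "_synthetic"), n),
             density_per_ha = dens, pct_mating = y, pct_spawning = sp,
             stringsAsFactors = FALSE)
}
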