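ll3_ref <- function(x, b, d, e) d / (1 + exp(b * (log(x) - log(e))))
asy_ref <- function(x, d, e) d * (1 - exp(-x / e))

test_that("censoring drops exactly the prescribed records, idempotently", {
  obs <- data.frame(source = "s",
                    density_per_ha = c(500, 50, 500, 120, 80),
                    pct_mating = c(0, 0, 12, 0, 5),
                    pct_spawning = c(4, 0, 6, 0, 0))
  cm <- censor_mating(obs)
  expect_equal(cm$density_per_ha, c(50, 500, 80))  # order preserved
  expect_identical(censor_mating(cm), cm)          # idempotent
  cs <- censor_spawn_vs_mating(obs)
  expect_equal(cs$density_per_ha, c(50, 500, 120, 80))
  expect_identical(censor_spawn_vs_mating(cs), cs)
})

test_that("log-logistic fit recovers noise-free parameters to 1e-3", {
  x <- conch_densities()
  y <- ll3_ref(x, b = -2, d = 10, e = 64)
  fit <- fit_log_logistic3(x, y)
  expect_true(fit$converged)
  co <- coef(fit)
  expect_equal(co[["b"]], -2, tolerance = 1e-3)
  expect_equal(co[["d"]], 10, tolerance = 1e-3)
  expect_equal(co[["e"]], 64, tolerance = 1e-3)
  # ED50 definition: f(e) = d/2
  expect_equal(predict(fit, co[["e"]]), co[["d"]] / 2, tolerance = 1e-9)
  expect_error(fit_log_logistic3(c(-1, 2, 3, 4), 1:4), "positive")
  expect_error(fit_log_logistic3(c(1, 2), c(1, 2)), "at least 4")
})

test_that("steep survey-like curves are recovered within 3 SE under noise", {
  # Survey-style continuous densities: with near-step curves, data inside
  # the transition are what identify the ED50 (the ten standard grid
  # levels alone only bracket it between adjacent levels).
  set.seed(27)
  dens <- round(10^runif(130, 1, 3.4))
  for (src in c("bahamas", "florida")) {
    spec <- fixture_spec(src, noise_sd = 2, records_per_density = 1,
                         densities = dens,
                         zero_inflation = 0, spawning = FALSE, seed = 8)
    obs <- generate_observations(spec)
    fit <- fit_log_logistic3(obs$density_per_ha, obs$pct_mating)
    expect_true(fit$converged)
    expect_lt(abs(coef(fit)[["d"]] - spec$d), 3 * fit$se[["d"]])
    expect_lt(abs(coef(fit)[["e"]] - spec$e), 3 * fit$se[["e"]])
  }
})

test_that("asymptotic regression recovers its parameters and limits", {
  x <- seq(0, 60, by = 4)
  y <- asy_ref(x, d = 11.89, e = 12.15)
  fit <- fit_asymptotic2(x, y)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["d"]], 11.89, tolerance = 1e-3)
  expect_equal(coef(fit)[["e"]], 12.15, tolerance = 1e-3)
  expect_equal(predict(fit, 0), 0)                       # lower limit
  expect_equal(predict(fit, 1e9), coef(fit)[["d"]])      # plateau
  # noisy recovery within 3 SE
  set.seed(16)
  y2 <- pmax(y + rnorm(length(y), 0, 1), 0)
  fit2 <- fit_asymptotic2(x, y2)
  expect_lt(abs(coef(fit2)[["d"]] - 11.89), 3 * fit2$se[["d"]])
  expect_lt(abs(coef(fit2)[["e"]] - 12.15), 3 * fit2$se[["e"]])
})

test_that("fit objects expose standard modelling methods", {
  x <- conch_densities()
  set.seed(17)
  y <- pmax(ll3_ref(x, -3, 10, 80) + rnorm(10, 0, 0.5), 0)
  fit <- fit_log_logistic3(x, y)
  expect_s3_class(fit, "conch_drfit")
  expect_named(coef(fit), c("b", "d", "e"))
  expect_equal(length(residuals(fit)), 10)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_equal(fit$df, 7)
  expect_equal(unname(fit$t_value), unname(coef(fit) / fit$se))
  expect_equal(unname(fit$p_value),
               unname(2 * pt(abs(fit$t_value), 7, lower.tail = FALSE)))
  expect_output(print(fit), "log_logistic_3")
})

test_that("interpolation is exact at knots and linear in log10 density", {
  knots <- data.frame(density = c(100, 1000), pct = c(10, 20))
  expect_equal(interpolate_at(knots, c(100, 1000)), c(10, 20))
  expect_equal(interpolate_at(knots, 10^2.5), 15)
  # no extrapolation
  expect_true(is.na(interpolate_at(knots, 50)))
  # duplicate knots averaged, unsorted input sorted
  k2 <- data.frame(density = c(1000, 100, 100), pct = c(20, 8, 12))
  expect_equal(interpolate_at(k2, 100), 10)
  # refinement: piecewise-linear in log10 reproduced from first principles
  set.seed(18)
  d <- sort(10^runif(8, 0.5, 3.5))
  p <- runif(8, 0, 100)
  q <- 10^runif(50, log10(min(d)), log10(max(d)))
  got <- interpolate_at(data.frame(d, p), q)
  for (i in seq_along(q)) {
    j <- findInterval(log10(q[i]), log10(d), rightmost.closed = TRUE)
    w <- (log10(q[i]) - log10(d[j])) / (log10(d[j + 1]) - log10(d[j]))
    expect_lt(abs(got[i] - ((1 - w) * p[j] + w * p[j + 1])), 1e-9)
  }
})

test_that("goodness-of-fit identities hold to machine precision", {
  g0 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(g0$SSR, g0$MSE, g0$RMSE), c(0, 0, 0))
  g <- goodness_of_fit(c(0, 0), c(3, 4))
  expect_equal(g$SSR, 25)
  expect_equal(g$MSE, 12.5)
  expect_equal(g$RMSE, sqrt(12.5))
  set.seed(19)
  pred <- rnorm(40)
  obs <- rnorm(40)
  gg <- goodness_of_fit(pred, obs)
  expect_equal(gg$SSR, sum((obs - pred)^2))
  expect_equal(gg$RMSE^2, gg$MSE, tolerance = 1e-15)
  expect_equal(gg$MSE * gg$n, gg$SSR, tolerance = 1e-15)
  # missing predictions dropped pairwise
  gna <- goodness_of_fit(c(NA, 0), c(1, 3))
  expect_equal(gna$n, 1)
  expect_equal(gna$SSR, 9)
  expect_error(goodness_of_fit(c(NA, NA), c(1, 2)), "no complete")
})

test_that("superiority compares SSRs and Bonferroni-corrected residual tests", {
  r <- c(1, -2, 1.5, -0.5, 2)
  same <- superiority(r, r)
  expect_false(same$superior)
  expect_false(same$significant)
  set.seed(20)
  reg <- rnorm(20, 0, 2)
  sup <- superiority(reg / 2, reg, n_comparisons = 12)
  expect_true(sup$superior)
  expect_equal(sup$threshold, 0.05 / 12)
  expect_equal(sup$threshold, 0.0041667, tolerance = 1e-4)
  expect_error(superiority(1:3, 1:4), "equal length")
})

test_that("fraction_superior recognises the generating mechanism", {
  # Synthetic design-results whose curves are double-sigmoid in log10
  # density -- shapes a single log-logistic regression cannot capture, so
  # a mechanistic curve that generated the observations can beat it.
  dens <- conch_densities()
  two_sig <- function(x, d1, c1, d2, c2)
    d1 / (1 + exp(-3 * (log10(x) - c1))) +
      d2 / (1 + exp(-8 * (log10(x) - c2)))
  combos <- expand.grid(speed = c("low", "med"), tau = c(0, 10, 25, 50),
                        stringsAsFactors = FALSE)
  combos$d1 <- c(10, 16, 8, 12, 7, 10, 5, 7)
  combos$c1 <- c(1.2, 1.1, 1.4, 1.3, 1.3, 1.4, 1.6, 1.5)
  combos$d2 <- c(9, 12, 8, 10, 8, 9, 6, 7)
  combos$c2 <- c(3.0, 2.9, 3.1, 3.0, 3.2, 3.1, 3.3, 3.2)
  mk_results <- function() {
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      data.frame(design_index = NA, density = dens,
                 speed = combos$speed[i], rest = "zero", tracking = FALSE,
                 pd_max = 0.5, tau = combos$tau[i], barrier = "none",
                 mean_pct_mating = two_sig(dens, combos$d1[i], combos$c1[i],
                                           combos$d2[i], combos$c2[i]),
                 ci_lo = NA, ci_hi = NA, mean_pct_spawning = 0,
                 sp_ci_lo = NA, sp_ci_hi = NA, replicates = 10)
    }))
  }
  res <- mk_results()
  key <- do.call(paste, c(res[c("speed", "rest", "tracking", "pd_max",
                                "tau", "barrier")], sep = "|"))
  gen_key <- unique(key)[5]   # observations come from combo 5's curve
  gen_curve <- res[key == gen_key, c("density", "mean_pct_mating")]

  # noise-free observations on the generating curve: that combo is
  # superior by construction, a flat curve is not
  od0 <- c(20, 60, 120, 300, 800, 2000)
  obs0 <- data.frame(source = "syn", density_per_ha = od0,
                     pct_mating = interpolate_at(gen_curve, od0))
  fs0 <- fraction_superior(res, obs0)
  expect_true(fs0$table$superior[fs0$table$combo == gen_key])

  hits <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    set.seed(100 + s)
    od <- rep(od0, each = 4)
    obs <- data.frame(source = "syn", density_per_ha = od,
                      pct_mating = pmax(interpolate_at(gen_curve, od) +
                                          rnorm(length(od), 0, 0.75), 0))
    fs <- fraction_superior(res, obs)
    if (fs$table$superior[fs$table$combo == gen_key]) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)

  # all-zero simulated curves never beat a well-fitting regression
  res0 <- mk_results()
  res0$mean_pct_mating <- 0
  set.seed(222)
  od <- rep(c(20, 60, 120, 300, 800), each = 5)
  obs <- data.frame(source = "syn", density_per_ha = od,
                    pct_mating = pmax(ll3_ref(od, -3, 10, 80) +
                                        rnorm(length(od), 0, 1), 0))
  fsz <- fraction_superior(res0, obs)
  expect_equal(fsz$pct_superior, 0)
})
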