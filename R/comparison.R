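#' Censor non-mating records above a density threshold
#'
#' Removes observations with zero percent mating at densities above the
#' threshold (default 100 adults/ha, the critical density above which
#' mating is expected); all other records are kept in their original
#' order.  Idempotent.
#'
#' @param observations data.frame with at least `density_per_ha` and
#'   `pct_mating`.
#' @param density_threshold Density above which zero-mating records are
#'   dropped.
#' @return The censored data.frame.
#' @export
censor_mating <- function(observations, density_threshold = 100) {
  drop <- observations$pct_mating == 0 &
    observations$density_per_ha > density_threshold
  out <- observations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Censor spawning-without-mating records
#'
#' Removes observations reporting positive spawning at zero mating.
#'
#' @param observations data.frame with `pct_mating` and `pct_spawning`.
#' @return The censored data.frame.
#' @export
censor_spawn_vs_mating <- function(observations) {
  drop <- observations$pct_mating == 0 & observations$pct_spawning > 0
  out <- observations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

ll3 <- function(x, b, d, e) d / (1 + exp(b * (log(x) - log(e))))
asy2 <- function(x, d, e) d * (1 - exp(-x / e))

# package an nlsLM fit into the common dose-response fit object
drfit_from_nls <- function(fit, x, y, model, n_par) {
  s <- summary(fit)
  co <- s$coefficients
  structure(list(model = model,
                 coefficients = setNames(co[, "Estimate"], rownames(co)),
                 se = setNames(co[, "Std. Error"], rownames(co)),
                 t_value = setNames(co[, "t value"], rownames(co)),
                 p_value = setNames(co[, "Pr(>|t|)"], rownames(co)),
                 residual_se = s$sigma, df = length(y) - n_par,
                 residuals = as.numeric(y - fitted(fit)),
                 fitted = as.numeric(fitted(fit)),
                 x = x, y = y, vcov = vcov(fit),
                 ssr = sum((y - fitted(fit))^2),
                 converged = TRUE),
            class = "conch_drfit")
}

failed_drfit <- function(model, x, y, msgs) {
  structure(list(model = model, coefficients = NULL, converged = FALSE,
                 diagnostics = msgs, x = x, y = y),
            class = "conch_drfit")
}

#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = d / (1 + exp(b * (log x - log e)))` (lower
#' limit fixed at 0; `e` is the ED50, `d` the upper asymptote, `b` the
#' slope).  Because fitted slopes can be extremely steep (near-step
#' curves), the Levenberg-Marquardt optimiser is multi-started from
#' `b0 in {-1, -5, -50}` with `d0 = max(y)` and `e0` the x nearest
#' half-maximum; the converged start with the lowest SSR wins.  Standard
#' errors come from the Jacobian at the optimum; t and two-sided p values
#' use `df = n - 3`.
#'
#' @param x Densities (must be positive).
#' @param y Percentages (0-100 scale).
#' @return Object of class `conch_drfit`; when no start converges the
#'   object has `converged = FALSE` and a `diagnostics` field.
#' @export
fit_log_logistic3 <- function(x, y) {
  if (any(x <= 0)) stop("x must be positive for the log-logistic model")
  if (length(x) < 4 || length(unique(x)) < 3)
    stop("need at least 4 points with 3 distinct x values")
  d0 <- max(y)
  e0 <- x[which.min(abs(y - d0 / 2))]
  if (e0 <= 0) e0 <- median(x)
  dat <- data.frame(x = x, y = y)
  best <- NULL
  msgs <- character(0)
  for (b0 in c(-1, -5, -50)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d / (1 + exp(b * (log(x) - log(e)))),
                        data = dat,
                        start = list(b = b0, d = d0, e = e0),
                        lower = c(b = -Inf, d = 0, e = min(x) * 1e-6),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-10)),
      error = function(err) conditionMessage(err))
    if (is.character(fit)) {
      msgs <- c(msgs, fit)
      next
    }
    ssr <- sum(residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr - 1e-12)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(failed_drfit("log_logistic_3", x, y, msgs))
  drfit_from_nls(best$fit, x, y, "log_logistic_3", 3)
}

#' Fit a two-parameter asymptotic regression
#'
#' Least-squares fit of `f(x) = d * (1 - exp(-x / e))` (lower limit fixed
#' at 0; `d` the plateau, `e` the rate constant), typically used here for
#' percent spawning against percent mating.  Multi-started
#' Levenberg-Marquardt; inference with `df = n - 2`.
#'
#' @param x Predictor (e.g. percent mating).
#' @param y Response (e.g. percent spawning).
#' @return Object of class `conch_drfit`.
#' @export
fit_asymptotic2 <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  d0 <- max(y)
  pos <- x[x > 0]
  e0s <- unique(pmax(c(if (length(pos)) quantile(pos, 0.25), median(x),
                       max(x) / 3), 1e-3))
  dat <- data.frame(x = x, y = y)
  best <- NULL
  msgs <- character(0)
  for (e0 in e0s) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d * (1 - exp(-x / e)), data = dat,
                        start = list(d = max(d0, 1e-6), e = e0),
                        lower = c(d = 0, e = 1e-9),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-10)),
      error = function(err) conditionMessage(err))
    if (is.character(fit)) {
      msgs <- c(msgs, fit)
      next
    }
    ssr <- sum(residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr - 1e-12)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(failed_drfit("asymptotic_2", x, y, msgs))
  drfit_from_nls(best$fit, x, y, "asymptotic_2", 2)
}

#' @export
coef.conch_drfit <- function(object, ...) object$coefficients

#' @export
vcov.conch_drfit <- function(object, ...) object$vcov

#' @export
residuals.conch_drfit <- function(object, ...) object$residuals

#' Predict from a fitted dose-response curve
#'
#' @param object A `conch_drfit`.
#' @param newdata Numeric vector of predictor values (defaults to the
#'   fitting data).
#' @param ... Unused.
#' @return Predicted percentages.
#' @export
predict.conch_drfit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  x <- if (is.null(newdata)) object$x else newdata
  p <- object$coefficients
  if (object$model == "log_logistic_3")
    ll3(x, p[["b"]], p[["d"]], p[["e"]])
  else
    asy2(x, p[["d"]], p[["e"]])
}

#' @export
print.conch_drfit <- function(x, ...) {
  cat("Dose-response fit:", x$model, "(lower limit 0)\n")
  if (!x$converged) {
    cat("  DID NOT CONVERGE\n")
    return(invisible(x))
  }
  print(round(cbind(Estimate = x$coefficients, `Std. Error` = x$se,
                    `t value` = x$t_value, `p value` = x$p_value), 4))
  cat(sprintf("Residual standard error: %.4f (%d degrees of freedom)\n",
              x$residual_se, x$df))
  invisible(x)
}

#' @export
summary.conch_drfit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.conch_drfit <- function(x, ..., log_axis = NULL) {
  if (is.null(log_axis)) log_axis <- x$model == "log_logistic_3"
  xv <- x$x
  if (log_axis) {
    plot(log10(xv), x$y, xlab = "log10 x", ylab = "y", ...)
    xs <- 10^seq(log10(min(xv)), log10(max(xv)), length.out = 200)
    lines(log10(xs), predict(x, xs), col = 2)
  } else {
    plot(xv, x$y, xlab = "x", ylab = "y", ...)
    xs <- seq(min(xv), max(xv), length.out = 200)
    lines(xs, predict(x, xs), col = 2)
  }
  invisible(x)
}

#' Interpolate a simulated density curve at query densities
#'
#' Piecewise-linear interpolation of percent mating/spawning between
#' simulated density knots, on the log10-density axis by default (matching
#' how the curves are plotted and compared).  Exact at knots; queries
#' outside the knot range return `NA` (no extrapolation).  Unsorted knots
#' are sorted; duplicate knot densities are averaged.
#'
#' @param sim_curve data.frame whose first two columns are density and
#'   percent (e.g. `density`, `mean_pct_mating`).
#' @param query_densities Densities at which to evaluate.
#' @param log_axis Interpolate in log10(density) (default) or linear
#'   density.
#' @return Numeric vector of predicted percentages (NA outside range).
#' @export
interpolate_at <- function(sim_curve, query_densities, log_axis = TRUE) {
  d <- sim_curve[[1]]
  p <- sim_curve[[2]]
  if (length(d) < 2) stop("need at least 2 knots")
  agg <- tapply(p, d, mean)
  dk <- as.numeric(names(agg))
  pk <- as.numeric(agg)
  o <- order(dk)
  dk <- dk[o]; pk <- pk[o]
  tx <- if (log_axis) log10(dk) else dk
  qx <- if (log_axis) log10(query_densities) else query_densities
  approx(tx, pk, xout = qx, rule = 1)$y
}

#' Goodness-of-fit summaries
#'
#' `SSR = sum((obs - pred)^2)`, `MSE = SSR / n`, `RMSE = sqrt(MSE)`.
#' Pairs with missing predictions are dropped.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Object of class `conch_gof`: list `SSR`, `MSE`, `RMSE`, `n`,
#'   `residuals` (obs - pred on the retained pairs).
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  keep <- !is.na(predicted) & !is.na(observed)
  if (!any(keep)) stop("no complete prediction/observation pairs")
  r <- observed[keep] - predicted[keep]
  n <- sum(keep)
  ssr <- sum(r^2)
  structure(list(SSR = ssr, MSE = ssr / n, RMSE = sqrt(ssr / n), n = n,
                 residuals = r, kept = which(keep)),
            class = "conch_gof")
}

#' @export
print.conch_gof <- function(x, ...) {
  cat(sprintf("GoF: SSR %.4g, MSE %.4g, RMSE %.4g (n = %d)\n",
              x$SSR, x$MSE, x$RMSE, x$n))
  invisible(x)
}

#' Superiority of a simulation fit over a regression fit
#'
#' A simulation is flagged `superior` when its SSR on the shared
#' observations is strictly smaller than the regression's (ties are not
#' superior).  Separately, the residuals are compared with a paired t-test
#' on absolute residuals (primary; a Welch two-sample variant on absolute
#' residuals is selectable) at the Bonferroni-corrected threshold
#' `alpha / n_comparisons`.
#'
#' @param sim_residuals,reg_residuals Residual vectors aligned to the same
#'   observations.
#' @param alpha Family-wise significance level.
#' @param n_comparisons Number of comparisons for Bonferroni correction.
#' @param method `"paired_abs"` or `"welch"`.
#' @return List: `superior`, `p_value`, `significant`, `threshold`,
#'   `ssr_sim`, `ssr_reg`.
#' @export
superiority <- function(sim_residuals, reg_residuals, alpha = 0.05,
                        n_comparisons = 1,
                        method = c("paired_abs", "welch")) {
  method <- match.arg(method)
  if (length(sim_residuals) != length(reg_residuals))
    stop("residual vectors must have equal length")
  ssr_sim <- sum(sim_residuals^2)
  ssr_reg <- sum(reg_residuals^2)
  thr <- alpha / n_comparisons
  p <- tryCatch({
    if (method == "paired_abs")
      t.test(abs(sim_residuals), abs(reg_residuals), paired = TRUE)$p.value
    else
      t.test(abs(sim_residuals), abs(reg_residuals), var.equal = FALSE)$p.value
  }, error = function(e) NA_real_)
  list(superior = ssr_sim < ssr_reg,
       p_value = p,
       significant = !is.na(p) && p < thr,
       threshold = thr, ssr_sim = ssr_sim, ssr_reg = ssr_reg)
}

#' Fraction of mechanistic simulations fitting observations better than a
#' dose-response regression
#'
#' For each mechanistic combination in a design-results table (all rows
#' sharing the same speed/rest/tracking/pd_max/tau/barrier levels across
#' densities), the simulated percent-mating curve is interpolated at the
#' observed densities and its goodness of fit is compared with a censored
#' log-logistic regression fit to the same observations.
#'
#' @param design_results Data.frame from [run_design()].
#' @param observations Observation data.frame (`density_per_ha`,
#'   `pct_mating`, ...).
#' @param censor Apply [censor_mating()] before fitting.
#' @param density_threshold Censoring threshold.
#' @param alpha Significance level for the Bonferroni-corrected tests.
#' @param log_axis Interpolation axis (see [interpolate_at()]).
#' @return List: `pct_superior`, per-combo `table`, and the regression
#'   `fit`.
#' @export
fraction_superior <- function(design_results, observations, censor = TRUE,
                              density_threshold = 100, alpha = 0.05,
                              log_axis = TRUE) {
  obs <- if (censor) censor_mating(observations, density_threshold)
         else observations
  fit <- fit_log_logistic3(obs$density_per_ha, obs$pct_mating)
  if (!fit$converged) stop("regression fit did not converge")
  reg_pred <- predict(fit, obs$density_per_ha)
  key_cols <- c("speed", "rest", "tracking", "pd_max", "tau", "barrier")
  key <- do.call(paste, c(design_results[key_cols], sep = "|"))
  combos <- unique(key)
  m <- length(combos)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    sub <- design_results[key == combos[i], , drop = FALSE]
    pred <- interpolate_at(sub[, c("density", "mean_pct_mating")],
                           obs$density_per_ha, log_axis = log_axis)
    keep <- !is.na(pred)
    if (!any(keep))
      stop("no overlap between simulated densities and observations")
    sim_res <- obs$pct_mating[keep] - pred[keep]
    reg_res <- obs$pct_mating[keep] - reg_pred[keep]
    sup <- superiority(sim_res, reg_res, alpha = alpha, n_comparisons = m)
    g <- goodness_of_fit(pred[keep], obs$pct_mating[keep])
    rows[[i]] <- data.frame(combo_id = i, combo = combos[i],
                            SSR_sim = g$SSR, RMSE_sim = g$RMSE,
                            SSR_reg = sup$ssr_reg,
                            RMSE_reg = sqrt(sup$ssr_reg / g$n),
                            superior = sup$superior,
                            p_value = sup$p_value,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  list(pct_superior = 100 * mean(tab$superior), table = tab, fit = fit)
}
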