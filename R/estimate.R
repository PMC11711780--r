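#' Default cost weights
#'
#' Flow sites are weighted equally. Pressure residuals are scaled so that a
#' 1 mmHg error contributes as much as a whole-waveform error of 1% of the
#' site's peak flow; without the cuff-pressure terms the compliances and
#' resistances would only be identifiable up to a common pressure gauge.
#'
#' @return named list with elements `flow` (named vector, one weight per
#'   site) and `pressure` (scalar).
#' @export
default_weights <- function() {
  list(flow = c(mitral_valve = 1, aortic_valve = 1, ascending_aorta = 1),
       pressure = 1)
}

# Residual vector of one parameter set against a bundle. Simulated flows are
# resampled onto the measurement grids (periodic linear interpolation) so the
# cost does not depend on solver step control; per-site residuals are
# normalized by the peak measured flow and by sqrt(n) so each site enters as
# its mean squared fractional error. Pressure residuals are
# 0.01 * (simulated max/min aortic pressure - SBP/DBP).
.residuals <- function(params, bundle, weights = default_weights(), ...) {
  sim <- simulate_model(params, ...)
  Tc <- bundle$T_cycle
  res <- c()
  for (site in names(weights$flow)) {
    w <- bundle$waveforms[[site]]
    qs <- periodic_interp(sim$time, switch(site,
            mitral_valve = sim$q_mv, aortic_valve = sim$q_av,
            ascending_aorta = sim$q_aa), Tc, w$time)
    peak <- max(abs(w$flow))
    res <- c(res, sqrt(weights$flow[[site]] / length(w$time)) *
                    (qs - w$flow) / peak)
  }
  res <- c(res,
           sqrt(weights$pressure) * 0.01 * (max(sim$p_aa) - bundle$sbp),
           sqrt(weights$pressure) * 0.01 * (min(sim$p_aa) - bundle$dbp))
  list(residuals = res, sim = sim)
}

#' Cost of a parameter set against a measurement bundle
#'
#' Simulates the model and scores it against the bundle's three flow
#' waveforms and cuff pressures. Components: per-site flow residual sum of
#' squares (mL^2/s^2), systolic and diastolic aortic-pressure residuals
#' (mmHg), and the dimensionless weighted total actually minimized by
#' [estimate()] (mean squared fractional flow errors plus scaled squared
#' pressure errors).
#'
#' @param params a `model_parameters` object; its simulation must converge.
#' @param bundle a [measurement_bundle()].
#' @param weights see [default_weights()].
#' @param ... passed to [simulate_model()].
#' @return a `cost_breakdown` list: `flow_rss` (named, mL^2/s^2),
#'   `sbp_residual`, `dbp_residual` (mmHg), `components` (normalized,
#'   dimensionless), `total`. If the simulation fails, `total` is `Inf` and
#'   `message` carries the diagnostic.
#' @export
cost <- function(params, bundle, weights = default_weights(), ...) {
  r <- tryCatch(.residuals(params, bundle, weights, ...),
                error = function(e) e)
  if (inherits(r, "error"))
    return(structure(list(flow_rss = NULL, sbp_residual = NA_real_,
                          dbp_residual = NA_real_, components = NULL,
                          total = Inf, message = conditionMessage(r)),
                     class = "cost_breakdown"))
  sim <- r$sim
  Tc <- bundle$T_cycle
  flow_rss <- components <- c()
  for (site in names(weights$flow)) {
    w <- bundle$waveforms[[site]]
    qs <- periodic_interp(sim$time, switch(site,
            mitral_valve = sim$q_mv, aortic_valve = sim$q_av,
            ascending_aorta = sim$q_aa), Tc, w$time)
    flow_rss[site] <- sum((qs - w$flow)^2)
    components[site] <- mean(((qs - w$flow) / max(abs(w$flow)))^2)
  }
  sbp_res <- max(sim$p_aa) - bundle$sbp
  dbp_res <- min(sim$p_aa) - bundle$dbp
  components["sbp"] <- (0.01 * sbp_res)^2
  components["dbp"] <- (0.01 * dbp_res)^2
  wts <- c(weights$flow, sbp = weights$pressure, dbp = weights$pressure)
  structure(list(flow_rss = flow_rss, sbp_residual = sbp_res,
                 dbp_residual = dbp_res, components = components,
                 total = sum(wts[names(components)] * components),
                 message = NULL),
            class = "cost_breakdown")
}

#' Personalize the subject-specific parameters against a measurement bundle
#'
#' Bound-constrained nonlinear least squares on the 23 subject-specific
#' parameters (in coordinates normalized to their bounds), matching the three
#' measured flow waveforms and the cuff pressures. `EOA`, `A_LVOT` and the
#' maximal LV elastance start at their directly derived values and may move
#' at most +/- 10%; the cycle length is taken from the bundle and never
#' optimized. Optionally restarts from additional Latin-hypercube points
#' within the bounds and returns the best local optimum; the whole procedure
#' is deterministic under `seed`.
#'
#' @param bundle a [measurement_bundle()].
#' @param defaults defaults (and bounds) for the non-derived parameters.
#' @param seed integer seed controlling the Latin-hypercube restarts.
#' @param n_starts maximum number of optimization starts (1 = the assembled
#'   measurement-derived start only).
#' @param restart_threshold cost below which further restarts are skipped:
#'   starts are attempted in order (derived start first, then the
#'   Latin-hypercube points) until the best total cost falls below this
#'   value or `n_starts` is exhausted.
#' @param weights see [default_weights()].
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param verbose log per-start best costs.
#' @param ... passed to [simulate_model()] for every cost evaluation.
#' @return an `estimation_result`: `params` (fitted `model_parameters`),
#'   `cost` (a `cost_breakdown`), `converged`, `niter`, `n_starts`,
#'   `start_costs`, and `at_bound` (names of parameters within 0.1% of a
#'   bound).
#' @export
estimate <- function(bundle, defaults = default_parameters(), seed = 1,
                     n_starts = 20, weights = default_weights(),
                     maxiter = 60, restart_threshold = 1e-3,
                     verbose = FALSE, ...) {
  start <- assemble_parameters(bundle, defaults)
  free_idx <- which(start$free)
  lo <- start$lower[free_idx]
  hi <- start$upper[free_idx]
  to_x <- function(vals) (vals - lo) / (hi - lo)
  from_x <- function(x) set_parameters(start,
              stats::setNames(lo + x * (hi - lo), start$name[free_idx]))

  n_res <- sum(vapply(bundle$waveforms, function(w) length(w$time), 0L)) + 2L
  fn <- function(x) {
    p <- from_x(x)
    r <- tryCatch(
      suppressWarnings(.residuals(p, bundle, weights, ...)$residuals),
      error = function(e) NULL)
    # optimizer-safe sentinel for failed simulations (fixed length)
    if (is.null(r) || any(!is.finite(r))) rep(1e3, n_res) else r
  }

  x0s <- list(to_x(start$value[free_idx]))
  if (n_starts > 1) {
    set.seed(seed)
    L <- lhs::randomLHS(n_starts - 1, length(free_idx))
    for (i in seq_len(nrow(L))) x0s[[i + 1]] <- L[i, ]
  }

  best <- NULL
  start_costs <- numeric(0)
  for (i in seq_along(x0s)) {
    fit <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(par = x0s[[i]], lower = rep(0, length(free_idx)),
                           upper = rep(1, length(free_idx)), fn = fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ptol = 1e-8, ftol = 1e-8,
                             # forward-difference step must clear the
                             # periodic-steady-state truncation noise
                             epsfcn = 1e-4)),
        # iteration-cap status is already reported via the converged flag
        warning = function(w) {
          if (grepl("maxiter", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) { start_costs[i] <- Inf; next }
    start_costs[i] <- fit$deviance
    if (verbose)
      message(sprintf("start %d/%d: cost %.3e (%d iterations)",
                      i, length(x0s), fit$deviance, fit$niter))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < restart_threshold) break
  }
  if (is.null(best) || !is.finite(best$deviance))
    return(structure(list(params = start, cost = NULL, converged = FALSE,
                          niter = 0L, n_starts = length(x0s),
                          start_costs = start_costs, at_bound = character(0)),
                     class = "estimation_result"))

  fitted <- from_x(best$par)
  xb <- best$par
  at_bound <- start$name[free_idx][xb < 1e-3 | xb > 1 - 1e-3]
  structure(list(params = fitted,
                 cost = cost(fitted, bundle, weights, ...),
                 converged = best$info %in% 1:4,
                 niter = best$niter, n_starts = length(x0s),
                 start_costs = start_costs, at_bound = at_bound),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> %s, %d iterations, %d start(s), cost %.3e\n",
              if (x$converged) "converged" else "NOT converged",
              x$niter, x$n_starts,
              if (is.null(x$cost)) Inf else x$cost$total))
  if (length(x$at_bound))
    cat("  at bound:", paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}
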