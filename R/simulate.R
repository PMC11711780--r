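#' Simulate the closed-loop model to periodic steady state
#'
#' Integrates the model cycle by cycle from a physiologic initial state until
#' the state at the start of a cycle matches the previous cycle start within a
#' relative drift tolerance, and returns the hemodynamics of the last
#' (converged) cycle.
#'
#' @param params a `model_parameters` object (see [default_parameters()]).
#' @param n_cycles_max maximum number of cycles to integrate (default 30).
#' @param periodicity_tol relative per-cycle state drift below which the
#'   solution is declared periodic (default 1e-3).
#' @param n_out number of output samples over the reported cycle (default 201).
#' @param compiled use the compiled right-hand side (default TRUE); `FALSE`
#'   integrates the pure-R reference [ode_rhs()].
#' @param rtol,atol solver tolerances (defaults 1e-6 and 1e-8).
#' @param state0 optional initial state; defaults to [initial_state()].
#' @return a `simulation_result`: list with `time` (s), `v_lv`, `v_la` (mL),
#'   `p_lv`, `p_la`, `p_aa`, `p_per` (mmHg), `q_mv`, `q_av`, `q_aa` (mL/s),
#'   `converged`, `cycles`, `drift`, and the `params` used. `p_aa` is the
#'   aortic pressure at the ascending aorta; `q_aa` the flow at the
#'   ascending-aorta measurement plane.
#' @examples
#' \donttest{
#' sim <- simulate_model(default_parameters())
#' sim$converged
#' max(sim$p_aa) - min(sim$p_aa)  # aortic pulse pressure (mmHg)
#' }
#' @export
simulate_model <- function(params, n_cycles_max = 30, periodicity_tol = 1e-3,
                           n_out = 201, compiled = TRUE,
                           rtol = 1e-6, atol = 1e-8, state0 = NULL) {
  validate_parameters(params)
  v <- parameter_values(params)
  Tc <- unname(v["t_cycle"])
  y <- state0 %||% initial_state(params)
  times <- seq(0, Tc, length.out = n_out)

  integrate_cycle <- function(y) {
    if (compiled) {
      out <- deSolve::lsoda(y, times, func = "hemo_derivs", parms = v,
                            dllname = "hemofit", initfunc = "hemo_initmod",
                            rtol = rtol, atol = atol, maxsteps = 20000)
    } else {
      out <- deSolve::lsoda(y, times, func = ode_rhs, parms = v,
                            rtol = rtol, atol = atol, maxsteps = 20000)
    }
    if (nrow(out) < length(times) || any(!is.finite(out)))
      stop_hemofit("integration failure at cycle time %g s",
                   out[nrow(out), 1])
    out
  }

  drift <- Inf
  cycles <- 0
  out <- NULL
  for (k in seq_len(n_cycles_max)) {
    out <- integrate_cycle(y)
    y_new <- out[nrow(out), -1]
    drift <- max(abs(y_new - y) / pmax(abs(y), 1))
    y <- y_new
    cycles <- k
    if (drift < periodicity_tol) break
  }
  converged <- drift < periodicity_tol

  st <- out[, -1, drop = FALSE]
  colnames(st) <- .STATE_NAMES
  tt <- out[, 1]
  e_lv <- elastance(tt %% Tc, .elastance_block(v, "lv"), Tc)
  e_la <- elastance((tt - v[["la_onset"]]) %% Tc, .elastance_block(v, "la"), Tc)
  res <- list(
    time  = tt,
    v_lv  = st[, "v_lv"], v_la = st[, "v_la"],
    p_lv  = v[["p_thorax"]] + e_lv * (st[, "v_lv"] - v[["lv_v0"]]),
    p_la  = v[["p_thorax"]] + e_la * (st[, "v_la"] - v[["la_v0"]]),
    p_aa  = (st[, "v_aa"] - v[["aa_v0"]]) / v[["c_aa"]],
    p_per = (st[, "v_per"] - v[["per_v0"]]) / v[["c_per"]],
    q_mv  = st[, "q_mv"], q_av = st[, "q_av"], q_aa = st[, "q_ao"],
    state = st,
    converged = converged, cycles = cycles, drift = drift,
    periodicity_tol = periodicity_tol,
    params = params)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(paste0("<simulation_result> %s after %d cycles ",
                     "(drift %.2e, tol %.0e)\n"),
              if (x$converged) "converged" else "NOT converged",
              x$cycles, x$drift, x$periodicity_tol))
  cat(sprintf("  aortic pressure %.1f/%.1f mmHg, LV volume %.1f-%.1f mL, SV %.1f mL\n",
              max(x$p_aa), min(x$p_aa), min(x$v_lv), max(x$v_lv),
              stroke_volume(x)))
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(time_s = x$time, p_lv_mmHg = x$p_lv, v_lv_mL = x$v_lv,
             q_mv_mL_s = x$q_mv, q_av_mL_s = x$q_av, q_aa_mL_s = x$q_aa,
             p_ao_mmHg = x$p_aa, p_la_mmHg = x$p_la, v_la_mL = x$v_la,
             p_per_mmHg = x$p_per)
}

#' Write a simulation result as CSV
#'
#' @param sim a `simulation_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Stroke volume of a converged cycle
#'
#' Trapezoidal integral of the aortic-valve flow over the reported cycle (mL).
#' @param sim a `simulation_result`.
#' @return stroke volume (mL).
#' @export
stroke_volume <- function(sim) trapz_(sim$time, sim$q_av)

#' Extract a measured-site flow waveform from a simulation
#'
#' Resamples a simulated flow trace onto a uniform grid with the given
#' sampling interval, mimicking the temporal resolution of an acquisition.
#'
#' @param sim a `simulation_result`.
#' @param site one of `"mitral_valve"`, `"aortic_valve"`, `"ascending_aorta"`.
#' @param dt sampling interval (s); default keeps the simulation grid.
#' @return a [flow_waveform()] object.
#' @export
sim_waveform <- function(sim, site = c("mitral_valve", "aortic_valve",
                                       "ascending_aorta"), dt = NULL) {
  site <- match.arg(site)
  q <- switch(site, mitral_valve = sim$q_mv, aortic_valve = sim$q_av,
              ascending_aorta = sim$q_aa)
  Tc <- parameter_values(sim$params)[["t_cycle"]]
  if (is.null(dt)) {
    t_out <- sim$time[-length(sim$time)]
    q_out <- q[-length(q)]
  } else {
    t_out <- cycle_grid(Tc, dt)
    q_out <- periodic_interp(sim$time[-length(sim$time)], q[-length(q)],
                             Tc, t_out)
  }
  flow_waveform(site, t_out, q_out, Tc)
}
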