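# Compartment network (closed loop, total volume conserved exactly):
#
#   pulmonary venous reservoir (c_pul)
#     --r_pul-->  left atrium (elastance)
#     --mitral valve: r_mv + l_mv, diode-->  left ventricle (elastance)
#     --aortic valve: energy-loss gradient + b_av inertia, diode-->
#   ascending aorta (c_aa)
#     --r_ao + l_ao--> peripheral Windkessel (c_per)
#     --r_per + r_ven--> back to the reservoir.
#
# The ascending-aorta measurement plane (upstream from the brachiocephalic
# trunk) is the flow leaving the ascending-aorta compartment, q_ao.
#
# State vector (8): v_lv, v_la, v_aa, v_per, v_pul, q_mv, q_av, q_ao.

.STATE_NAMES <- c("v_lv", "v_la", "v_aa", "v_per", "v_pul",
                  "q_mv", "q_av", "q_ao")

# Smooth valve gate: ~1 when open, ~0 when closed. A valve is open while the
# driving pressure is positive OR forward flow persists (inertial
# deceleration); backflow against a negative gradient is blocked by r_closed,
# leaving a documented leakage |q_leak| <= |dP|/r_closed (~0.01 mL/s at
# physiological pressures).
.valve_gate <- function(dp, q, dp_width) {
  sp <- stats::plogis(dp / dp_width)
  sq <- stats::plogis(q / 0.5)  # 0.5 mL/s flow half-width
  1 - (1 - sp) * (1 - sq)
}

#' Instantaneous compartment pressures
#'
#' @param state named state vector (see [ode_rhs()]).
#' @param t time within the cycle (s).
#' @param params a `model_parameters` object (or its [parameter_values()]).
#' @return named vector: `p_lv`, `p_la`, `p_aa`, `p_per`, `p_pul` (mmHg).
#' @export
compartment_pressures <- function(state, t, params) {
  v <- if (is.numeric(params)) params else parameter_values(params)
  Tc <- v[["t_cycle"]]
  e_lv <- elastance(t %% Tc, .elastance_block(v, "lv"), Tc)
  tau <- (t - v[["la_onset"]]) %% Tc
  e_la <- elastance(tau, .elastance_block(v, "la"), Tc)
  c(p_lv  = v[["p_thorax"]] + e_lv * (state[["v_lv"]] - v[["lv_v0"]]),
    p_la  = v[["p_thorax"]] + e_la * (state[["v_la"]] - v[["la_v0"]]),
    p_aa  = (state[["v_aa"]] - v[["aa_v0"]]) / v[["c_aa"]],
    p_per = (state[["v_per"]] - v[["per_v0"]]) / v[["c_per"]],
    p_pul = v[["p_pul0"]] + (state[["v_pul"]] - v[["v_pul0"]]) / v[["c_pul"]])
}

.elastance_block <- function(v, ch) {
  elastance_params(e_max = v[[paste0(ch, "_emax")]],
                   e_min = v[[paste0(ch, "_emin")]],
                   r_c = v[[paste0(ch, "_rc")]], r_r = v[[paste0(ch, "_rr")]],
                   alpha_s = v[[paste0(ch, "_alpha_s")]],
                   alpha_d = v[[paste0(ch, "_alpha_d")]],
                   t_max = v[[paste0(ch, "_tmax")]], v0 = v[[paste0(ch, "_v0")]],
                   T_cycle = v[["t_cycle"]])
}

#' ODE right-hand side of the closed-loop model (reference implementation)
#'
#' Pure-R right-hand side in the [deSolve::ode()] calling convention. The
#' packaged simulations use an equivalent compiled version; this function is
#' the readable reference and is exercised against it in the tests.
#'
#' @param t time (s).
#' @param state named numeric state vector of length 8
#'   (`v_lv, v_la, v_aa, v_per, v_pul, q_mv, q_av, q_ao`).
#' @param parms named vector of the 40 parameter values
#'   (from [parameter_values()]).
#' @return `list(dstate)` as required by deSolve.
#' @export
ode_rhs <- function(t, state, parms) {
  v <- parms
  if (any(!is.finite(state)))
    stop_hemofit("non-finite state at t = %g", t)
  p <- compartment_pressures(state, t, v)

  q_pul <- (p[["p_pul"]] - p[["p_la"]]) / v[["r_pul"]]

  # mitral valve: resistance + inertance, diode
  dp_mv <- p[["p_la"]] - p[["p_lv"]]
  g_mv <- .valve_gate(dp_mv, state[["q_mv"]], v[["dp_width"]])
  dq_mv <- (dp_mv - v[["r_mv"]] * state[["q_mv"]] -
              v[["r_closed"]] * (1 - g_mv) * state[["q_mv"]]) / v[["l_mv"]]

  # aortic valve: energy-loss gradient + inertial coefficient b_av, diode
  dp_av <- p[["p_lv"]] - p[["p_aa"]]
  kap <- .valve_kappa(v[["eoa"]], v[["a_lvot"]], v[["rho"]])
  g_av <- .valve_gate(dp_av, state[["q_av"]], v[["dp_width"]])
  if (v[["b_av"]] > 0) {
    dq_av <- (dp_av - kap * state[["q_av"]] * abs(state[["q_av"]]) -
                v[["r_av_open"]] * state[["q_av"]] -
                v[["r_closed"]] * (1 - g_av) * state[["q_av"]]) / v[["b_av"]]
  } else {
    # no inertial term: relax rapidly onto the algebraic energy-loss flow
    r0 <- v[["r_av_open"]]
    q_alg <- if (dp_av > 0)
      (-r0 + sqrt(r0^2 + 4 * kap * dp_av)) / (2 * kap) else 0
    dq_av <- (g_av * q_alg - state[["q_av"]]) / 1e-4
  }

  # aortic segment to the peripheral Windkessel
  dq_ao <- (p[["p_aa"]] - p[["p_per"]] - v[["r_ao"]] * state[["q_ao"]]) / v[["l_ao"]]

  # venous return closing the loop
  q_sys <- (p[["p_per"]] - p[["p_pul"]]) / (v[["r_per"]] + v[["r_ven"]])

  list(c(v_lv  = state[["q_mv"]] - state[["q_av"]],
         v_la  = q_pul - state[["q_mv"]],
         v_aa  = state[["q_av"]] - state[["q_ao"]],
         v_per = state[["q_ao"]] - q_sys,
         v_pul = q_sys - q_pul,
         q_mv  = dq_mv, q_av = dq_av, q_ao = dq_ao))
}

#' Physiologic initial state
#'
#' Starting point for the cycle-by-cycle integration: compartments filled to
#' typical diastolic pressures, all valve flows zero.
#'
#' @param params a `model_parameters` object.
#' @return named state vector of length 8.
#' @export
initial_state <- function(params) {
  v <- parameter_values(params)
  c(v_lv  = unname(v["lv_v0"]) + 8 / unname(v["lv_emin"]) * 0.8,
    v_la  = unname(v["la_v0"]) + 8 / unname(v["la_emin"]),
    v_aa  = unname(v["aa_v0"]) + 80 * unname(v["c_aa"]),
    v_per = unname(v["per_v0"]) + 80 * unname(v["c_per"]),
    v_pul = unname(v["v_pul0"]),
    q_mv = 0, q_av = 0, q_ao = 0)
}
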