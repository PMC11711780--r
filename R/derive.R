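#' Flow waveform at a measurement site
#'
#' One periodic, site-specific volumetric flow trace sampled over a single
#' cardiac cycle.
#'
#' @param site `"mitral_valve"`, `"aortic_valve"` or `"ascending_aorta"`.
#' @param time sample times (s), strictly increasing, all below `T_cycle`.
#' @param flow flow values (mL/s).
#' @param T_cycle cycle length (s).
#' @return a `flow_waveform` object.
#' @export
flow_waveform <- function(site = c("mitral_valve", "aortic_valve",
                                   "ascending_aorta"), time, flow, T_cycle) {
  site <- match.arg(site)
  if (length(time) != length(flow) || length(time) < 20)
    stop_hemofit("waveform needs >= 20 paired samples (got %d)", length(time))
  if (any(!is.finite(time)) || any(!is.finite(flow)))
    stop_hemofit("non-finite waveform samples")
  if (any(diff(time) <= 0)) stop_hemofit("waveform times must be strictly increasing")
  if (T_cycle <= 0 || time[length(time)] >= T_cycle)
    stop_hemofit("waveform times must stay below the cycle length T = %g", T_cycle)
  structure(list(site = site, time = as.numeric(time),
                 flow = as.numeric(flow), T_cycle = T_cycle),
            class = "flow_waveform")
}

#' Peak-velocity trace at the aortic valve
#'
#' Instantaneous maximal velocity at the valve (cm/s), sampled on the same
#' grid as the paired aortic-valve flow waveform.
#'
#' @param time sample times (s).
#' @param velocity velocities (cm/s).
#' @return a `velocity_trace` object.
#' @export
velocity_trace <- function(time, velocity) {
  if (length(time) != length(velocity))
    stop_hemofit("velocity trace: time and velocity lengths differ")
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity)),
            class = "velocity_trace")
}

#' Per-occasion measurement bundle
#'
#' All model inputs a single analysis occasion provides for one subject:
#' cycle length, end-systolic volume, valve areas, cuff pressures and the
#' three flow waveforms (plus, optionally, the peak-velocity trace from which
#' EOA can be re-derived).
#'
#' @param subject_id subject identifier.
#' @param occasion occasion tag: `"observer1_a"`, `"observer1_b"`,
#'   `"observer2"`, `"sgre"` or `"epi"`.
#' @param T_cycle cycle length (s).
#' @param esv LV end-systolic volume (mL).
#' @param eoa effective orifice area (cm^2).
#' @param a_lvot outflow-tract area (cm^2).
#' @param sbp,dbp brachial cuff pressures (mmHg).
#' @param waveforms named list with elements `mitral_valve`, `aortic_valve`,
#'   `ascending_aorta`, each a [flow_waveform()].
#' @param velocity optional [velocity_trace()] at the aortic valve.
#' @return a `measurement_bundle` object.
#' @export
measurement_bundle <- function(subject_id, occasion, T_cycle, esv, eoa, a_lvot,
                               sbp, dbp, waveforms, velocity = NULL) {
  occ <- c("observer1_a", "observer1_b", "observer2", "sgre", "epi")
  if (!occasion %in% occ)
    stop_hemofit("unknown occasion '%s'", occasion)
  if (T_cycle <= 0 || esv <= 0) stop_hemofit("T and ESV must be positive")
  if (!(eoa > 0 && eoa < a_lvot))
    stop_hemofit("bundle must satisfy 0 < EOA < A_LVOT")
  if (!(sbp > dbp && dbp > 0)) stop_hemofit("must have SBP > DBP > 0")
  need <- c("mitral_valve", "aortic_valve", "ascending_aorta")
  if (!all(need %in% names(waveforms)))
    stop_hemofit("missing waveform(s): %s",
                 paste(setdiff(need, names(waveforms)), collapse = ", "))
  for (s in need) {
    w <- waveforms[[s]]
    if (!inherits(w, "flow_waveform")) stop_hemofit("waveform %s has wrong type", s)
    if (abs(w$T_cycle - T_cycle) > 1e-9)
      stop_hemofit("waveform %s cycle length (%g) differs from bundle T (%g)",
                   s, w$T_cycle, T_cycle)
  }
  structure(list(subject_id = subject_id, occasion = occasion,
                 T_cycle = T_cycle, esv = esv, eoa = eoa, a_lvot = a_lvot,
                 sbp = sbp, dbp = dbp, waveforms = waveforms[need],
                 velocity = velocity),
            class = "measurement_bundle")
}

#' Effective orifice area from flow and peak velocity
#'
#' `EOA = SV / VTI` (cm^2): the stroke volume is the trapezoidal time integral
#' of the aortic-valve flow over the cycle, and the velocity-time integral is
#' the integral of the instantaneous maximal velocity over the systolic
#' support, defined as the contiguous region where the valve flow exceeds 1%
#' of its peak. The EOA is assumed constant over time.
#'
#' @param q_av aortic-valve [flow_waveform()].
#' @param v paired [velocity_trace()] (cm/s), same grid as `q_av`.
#' @return EOA (cm^2).
#' @export
derive_eoa <- function(q_av, v) {
  stopifnot(inherits(q_av, "flow_waveform"), inherits(v, "velocity_trace"))
  if (q_av$site != "aortic_valve")
    stop_hemofit("EOA derivation needs the aortic-valve waveform, got %s", q_av$site)
  if (length(v$time) != length(q_av$time) ||
      max(abs(v$time - q_av$time)) > 1e-9)
    stop_hemofit("flow and velocity traces are not on the same grid")
  sv <- net_flow(q_av)  # closed-cycle trapezoidal integral
  sys <- .systolic_support(q_av$flow)
  vti <- trapz_(v$time[sys], v$velocity[sys])
  if (vti <= 0) stop_hemofit("non-positive VTI (%g); cannot derive EOA", vti)
  sv / vti
}

# contiguous systolic support around the flow peak: q > 1% of peak, widened
# by one bracketing sample on each side so the trapezoidal integral keeps the
# rising and falling edge segments even on coarse acquisition grids
.systolic_support <- function(q) {
  thr <- 0.01 * max(q)
  above <- q > thr
  i_pk <- which.max(q)
  lo <- i_pk
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i_pk
  while (hi < length(q) && above[hi + 1]) hi <- hi + 1
  seq(max(lo - 1, 1), min(hi + 1, length(q)))
}

#' Maximal LV elastance from non-invasive measurements
#'
#' Single-beat estimate
#' \deqn{E_{max,LV} = 0.9\,\frac{SBP + \Delta P_{max}}{ESV - V0_{LV}},\qquad
#'   \Delta P_{max} = \frac{\rho}{2\,ELCo^2}\,\max(Q_{AV})^2\,\frac{0.06}{133.322},}
#' with the convective transvalvular gradient evaluated at peak aortic-valve
#' flow.
#'
#' @param bundle a [measurement_bundle()].
#' @param v0_lv unstressed LV volume (mL), default 10.
#' @param rho blood density (g/mL), default 1.06.
#' @return `E_max` of the LV (mmHg/mL).
#' @examples
#' # SBP 120, ESV 50, V0 10, peak AV flow 400, EOA 3, A_LVOT 4:
#' # PG_max ~ 0.265 mmHg, E_max ~ 2.706 mmHg/mL
#' @export
derive_emax_lv <- function(bundle, v0_lv = 10, rho = 1.06) {
  stopifnot(inherits(bundle, "measurement_bundle"))
  if (bundle$esv <= v0_lv)
    stop_hemofit("ESV (%g mL) must exceed V0_LV (%g mL)", bundle$esv, v0_lv)
  q_av <- bundle$waveforms$aortic_valve
  if (is.null(q_av)) stop_hemofit("missing aortic-valve waveform")
  pg_max <- valve_pressure_gradient(max(q_av$flow), 0, bundle$eoa,
                                    bundle$a_lvot, rho)
  0.9 * (bundle$sbp + pg_max) / (bundle$esv - v0_lv)
}

#' Assemble a personalized parameter set from a measurement bundle
#'
#' Pure function mapping one occasion's measurements onto the model parameter
#' table: the cycle length is fixed to the measured `T`; `EOA`, `A_LVOT` and
#' the maximal LV elastance are set to their directly derived values with
#' optimization bounds at +/- 10%; the remaining free parameters keep their
#' defaults and documented bounds; the fixed parameters are untouched.
#'
#' @param bundle a [measurement_bundle()].
#' @param defaults a `model_parameters` object, default [default_parameters()].
#' @param v0_lv unstressed LV volume used in the elastance derivation (mL).
#' @return a `model_parameters` object ready for [estimate()].
#' @export
assemble_parameters <- function(bundle, defaults = default_parameters(),
                                v0_lv = NULL) {
  stopifnot(inherits(bundle, "measurement_bundle"))
  v0 <- v0_lv %||% parameter_values(defaults)[["lv_v0"]]
  emax <- derive_emax_lv(bundle, v0_lv = v0,
                         rho = parameter_values(defaults)[["rho"]])
  p <- defaults
  # keep absolute timing consistent with the measured cycle length
  p <- rescale_cycle(p, bundle$T_cycle)
  p <- set_parameters(p, c(eoa = bundle$eoa, a_lvot = bundle$a_lvot,
                           lv_emax = emax, lv_v0 = v0))
  for (nm in c("eoa", "a_lvot", "lv_emax")) {
    i <- match(nm, p$name)
    p$lower[i] <- 0.9 * p$value[i]
    p$upper[i] <- 1.1 * p$value[i]
  }
  validate_parameters(p)
  p
}
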