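#' Transvalvular pressure gradient of the energy-loss aortic valve
#'
#' Net pressure gradient across the aortic valve as a function of
#' instantaneous flow,
#' \deqn{\Delta P = \frac{\rho}{2\,ELCo^2}\, Q\,|Q|\ \frac{0.06}{133.322}
#'       \;+\; B\,\frac{dQ}{dt},}
#' with flow in mL/s, areas in cm^2, density in g/mL and the result in mmHg.
#' The convective term is antisymmetric in `Q`; the optional inertial term
#' `B dQ/dt` can be switched off with `b = 0`.
#'
#' @param q instantaneous flow (mL/s); vectorized.
#' @param dqdt flow rate of change (mL/s^2).
#' @param eoa effective orifice area (cm^2).
#' @param a_lvot outflow-tract area (cm^2); must exceed `eoa`.
#' @param rho blood density (g/mL), default 1.06.
#' @param b inertial coefficient (mmHg s^2/mL), default 0 (convective only).
#' @return pressure gradient (mmHg).
#' @examples
#' valve_pressure_gradient(400, 0, eoa = 3, a_lvot = 4)  # ~0.265 mmHg
#' @export
valve_pressure_gradient <- function(q, dqdt = 0, eoa, a_lvot, rho = 1.06, b = 0) {
  elco <- derive_elco(eoa, a_lvot)
  rho / (2 * elco^2) * q * abs(q) * .PG_UNIT + b * dqdt
}

# Convective coefficient kappa such that the convective gradient is
# kappa * q * |q| (mmHg when q is in mL/s).
.valve_kappa <- function(eoa, a_lvot, rho) {
  rho / (2 * derive_elco(eoa, a_lvot)^2) * .PG_UNIT
}
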