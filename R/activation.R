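#' Elastance parameter block
#'
#' Bundles the eight parameters describing one time-varying-elastance chamber:
#' the maximal (end-systolic) elastance `e_max` and minimal (passive) elastance
#' `e_min` in mmHg/mL, the dimensionless contraction and relaxation rates `r_c`
#' and `r_r` (Hill exponents), the systolic and diastolic time constants
#' `alpha_s` and `alpha_d` (fractions of the cycle length), the time of
#' end-systole `t_max` (s, when the elastance peaks) and the unstressed chamber
#' volume `v0` (mL).
#'
#' @param e_max,e_min maximal and minimal elastance (mmHg/mL), `e_max > e_min > 0`.
#' @param r_c,r_r contraction / relaxation Hill exponents (> 0).
#' @param alpha_s,alpha_d systolic / diastolic time constants as fractions of
#'   the cycle length, in (0, 1).
#' @param t_max time of maximal elastance (s), in (0, `T_cycle`).
#' @param v0 unstressed volume (mL), >= 0.
#' @param T_cycle cycle length (s) used to validate `t_max`.
#' @return an object of class `elastance_params`.
#' @examples
#' p <- elastance_params(e_max = 2.7, e_min = 0.06, r_c = 1.32, r_r = 21.9,
#'                       alpha_s = 0.303, alpha_d = 0.508, t_max = 0.43,
#'                       v0 = 10, T_cycle = 1)
#' elastance(p$t_max, p, T_cycle = 1)  # == e_max
#' @export
elastance_params <- function(e_max, e_min, r_c, r_r, alpha_s, alpha_d,
                             t_max, v0, T_cycle) {
  vals <- c(e_max = e_max, e_min = e_min, r_c = r_c, r_r = r_r,
            alpha_s = alpha_s, alpha_d = alpha_d, t_max = t_max, v0 = v0)
  if (any(!is.finite(vals)))
    stop_hemofit("non-finite elastance parameter: %s",
                 paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (!(e_max > e_min)) stop_hemofit("e_max (%g) must exceed e_min (%g)", e_max, e_min)
  if (e_min <= 0) stop_hemofit("e_min must be positive")
  if (r_c <= 0 || r_r <= 0) stop_hemofit("Hill exponents r_c, r_r must be positive")
  if (alpha_s <= 0 || alpha_s >= 1 || alpha_d <= 0 || alpha_d >= 1)
    stop_hemofit("alpha_s and alpha_d must lie strictly in (0, 1)")
  if (t_max <= 0 || t_max >= T_cycle)
    stop_hemofit("t_max (%g) must lie strictly inside the cycle (0, %g)", t_max, T_cycle)
  if (v0 < 0) stop_hemofit("v0 must be non-negative")
  structure(as.list(vals), class = "elastance_params")
}

# Unnormalized double-Hill activation shape. Rising Hill factor with exponent
# r_c and time scale alpha_s*T, falling factor with exponent r_r and scale
# alpha_d*T.
.activation_shape <- function(t, p, T_cycle) {
  xs <- (t / (p$alpha_s * T_cycle))^p$r_c
  xd <- (t / (p$alpha_d * T_cycle))^p$r_r
  rise <- ifelse(is.infinite(xs), 1, xs / (1 + xs))
  fall <- ifelse(is.infinite(xd), 0, 1 / (1 + xd))
  rise * fall
}

#' Normalized chamber activation
#'
#' Dimensionless activation of a time-varying-elastance chamber: the product of
#' a rising and a falling Hill function, normalized so the activation is exactly
#' 1 at the time of end-systole `t_max`,
#' \deqn{g(t) = h(t)/h(t_{max}), \quad
#'       h(t) = \frac{(t/(\alpha_S T))^{R_C}}{1+(t/(\alpha_S T))^{R_C}}
#'              \cdot \frac{1}{1+(t/(\alpha_D T))^{R_R}}.}
#'
#' @param t times (s) in `[0, T_cycle)`; vectorized.
#' @param p an [elastance_params()] object.
#' @param T_cycle cycle length (s).
#' @return activation values in `[0, 1]`; 0 at `t = 0`, 1 at `t = t_max`.
#' @export
normalized_activation <- function(t, p, T_cycle) {
  h_peak <- .activation_shape(p$t_max, p, T_cycle)
  g <- .activation_shape(t, p, T_cycle) / h_peak
  if (any(!is.finite(g)))
    stop_hemofit(paste0("non-finite activation (overflow): check Hill exponents ",
                        "r_c = %g, r_r = %g"), p$r_c, p$r_r)
  g
}

#' Time-varying elastance
#'
#' `E(t) = e_min + (e_max - e_min) * g(t)` with `g` the
#' [normalized_activation()]; equals `e_min` at `t = 0` and `e_max` at
#' `t = t_max`.
#'
#' @inheritParams normalized_activation
#' @return elastance in mmHg/mL.
#' @export
elastance <- function(t, p, T_cycle) {
  p$e_min + (p$e_max - p$e_min) * normalized_activation(t, p, T_cycle)
}

#' Time at which the activation shape actually peaks
#'
#' Locates the argmax of the unnormalized double-Hill shape on `(0, T_cycle)`.
#' Parameter sets whose `t_max` equals this time have activation bounded by 1
#' everywhere; the synthetic-subject generator uses it to keep drawn parameter
#' sets self-consistent.
#'
#' @inheritParams normalized_activation
#' @return the peak time (s).
#' @export
activation_peak_time <- function(p, T_cycle) {
  stats::optimize(function(t) .activation_shape(t, p, T_cycle),
                  interval = c(1e-6, T_cycle - 1e-6), maximum = TRUE,
                  tol = 1e-10)$maximum
}
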