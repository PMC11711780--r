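# The model comprises 40 scalar parameters; 23 are flagged subject-specific
# (free) and 17 fixed. Of the free set, EOA, A_LVOT and the maximal LV
# elastance are derived directly from measurements and only allowed to move
# +/- 10% during optimization; the remaining 20 are tuned by the optimizer
# from the defaults below. The cycle length t_cycle is assigned per subject
# from the measurement but never optimized.

.PARAM_TABLE <- function() {
  # name, default, free, lower, upper, units
  p <- rbind(
    # -- aortic valve geometry ------------------------------------------------
    c("eoa",        3.5,    1, 1.0,    6.0),   # cm^2, effective orifice area
    c("a_lvot",     7.0,    1, 3.0,   10.0),   # cm^2, LV outflow tract area
    # -- LV time-varying elastance -------------------------------------------
    c("lv_emax",    2.4,    1, 1.0,    6.0),   # mmHg/mL
    c("lv_emin",    0.06,   1, 0.02,   0.15),  # mmHg/mL
    c("lv_rc",      2.0,   1, 0.8,    6.0),   # -
    c("lv_rr",      21.9,   1, 10,    40),     # -
    c("lv_alpha_s", 0.32,  1, 0.06,   0.45),  # fraction of cycle
    c("lv_alpha_d", 0.45,  1, 0.35,   0.70),  # fraction of cycle
    c("lv_tmax",    0.388, 1, 0.20,   0.65),  # s
    # -- LA time-varying elastance (on the atrial clock, shifted by la_onset) -
    c("la_emax",    0.35,   1, 0.15,   0.70),  # mmHg/mL
    c("la_emin",    0.15,   1, 0.05,   0.30),  # mmHg/mL
    c("la_rc",      2.0,    1, 1.0,    4.0),   # -
    c("la_rr",      20,     1, 10,    40),     # -
    c("la_alpha_s", 0.08,   1, 0.04,   0.15),  # fraction of cycle
    c("la_alpha_d", 0.16,   1, 0.08,   0.30),  # fraction of cycle
    c("la_tmax",    0.1336, 1, 0.05,   0.30),  # s, on the atrial clock
    c("la_onset",   0.78,   1, 0.60,   0.92),  # s, atrial activation onset
    # -- vessels --------------------------------------------------------------
    c("c_aa",       0.12,   1, 0.02,   0.40),  # mL/mmHg, ascending aorta
    c("r_ao",       0.035,  1, 0.008,  0.12),  # mmHg s/mL, aortic segment
    c("c_per",      1.7,    1, 0.5,    2.5),   # mL/mmHg, peripheral Windkessel
    c("r_per",      1.0,   1, 0.4,    2.0),   # mmHg s/mL, peripheral resistance
    # -- mitral valve ---------------------------------------------------------
    c("r_mv",       0.004,  1, 0.001,  0.02),  # mmHg s/mL
    c("l_mv",       5e-4,   1, 1e-4,   2e-3),  # mmHg s^2/mL
    # -- fixed parameters (17) ------------------------------------------------
    c("t_cycle",    1.0,    0, 0.4,    2.0),   # s, assigned from measurement
    c("lv_v0",      10,     0, 0,     30),     # mL, unstressed LV volume
    c("la_v0",      4,      0, 0,     20),     # mL, unstressed LA volume
    c("rho",        1.06,   0, 1.0,    1.1),   # g/mL, blood density
    c("b_av",       2.5e-3, 0, 0,      1e-2),  # mmHg s^2/mL, valve inertial coeff.
    c("l_ao",       1e-4,   0, 2e-5,   2e-2),  # mmHg s^2/mL
    c("r_av_open",  1.5e-2, 0, 0,      5e-2),  # mmHg s/mL, open-valve viscous loss
    c("r_pul",      0.03,   0, 0.01,   0.1),   # mmHg s/mL, pulmonary venous inflow
    c("r_ven",      0.03,   0, 0.01,   0.1),   # mmHg s/mL, venous return
    c("c_pul",      15,     0, 5,     50),     # mL/mmHg, pulmonary venous reservoir
    c("v_pul0",     300,    0, 100,  1000),    # mL, reservoir unstressed volume
    c("p_pul0",     7,      0, 2,     20),     # mmHg, reservoir operating pressure
    c("aa_v0",      55,     0, 10,   150),     # mL, unstressed ascending-aorta volume
    c("per_v0",     550,    0, 200, 1500),     # mL, unstressed peripheral volume
    c("r_closed",   1e4,    0, 1e3,   1e6),    # mmHg s/mL, closed-valve resistance
    c("dp_width",   0.1,    0, 0.01,   1),     # mmHg, valve sigmoid half-width
    c("p_thorax",   0,      0, -10,   10)      # mmHg, external chamber pressure
  )
  data.frame(name  = p[, 1],
             value = as.numeric(p[, 2]),
             free  = as.logical(as.numeric(p[, 3])),
             lower = as.numeric(p[, 4]),
             upper = as.numeric(p[, 5]),
             stringsAsFactors = FALSE)
}

#' Default model parameter set
#'
#' Returns the full 40-parameter set of the closed-loop model with
#' literature-typical healthy defaults, per-parameter free/fixed flags and
#' bounds. Exactly 23 parameters are flagged subject-specific (free); the
#' remaining 17 are fixed. Defaults can be overridden by name.
#'
#' @param ... named scalar overrides, e.g. `default_parameters(c_aa = 0.08)`.
#' @return a `model_parameters` object (data frame with columns `name`,
#'   `value`, `free`, `lower`, `upper`).
#' @examples
#' mp <- default_parameters()
#' sum(mp$free)   # 23 subject-specific parameters
#' @export
default_parameters <- function(...) {
  tab <- .PARAM_TABLE()
  class(tab) <- c("model_parameters", "data.frame")
  over <- list(...)
  if (length(over)) tab <- set_parameters(tab, unlist(over))
  validate_parameters(tab)
  tab
}

#' Named vector of parameter values
#' @param params a `model_parameters` object.
#' @return named numeric vector of the 40 values.
#' @export
parameter_values <- function(params) stats::setNames(params$value, params$name)

#' Update parameter values by name
#'
#' Pure update: returns a modified copy, bounds and flags untouched.
#'
#' @param params a `model_parameters` object.
#' @param values named numeric vector of replacements.
#' @return the updated `model_parameters` object.
#' @export
set_parameters <- function(params, values) {
  unknown <- setdiff(names(values), params$name)
  if (length(unknown))
    stop_hemofit("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  params$value[match(names(values), params$name)] <- as.numeric(values)
  params
}

#' Validate a model parameter set
#'
#' Checks the structural invariants: 23 free / 17 fixed split, positivity of
#' resistances, compliances and inertances, elastance ordering for both
#' chambers, valve-area ordering `0 < EOA < A_LVOT`, and bounds bracketing
#' values for the free parameters.
#'
#' @param params a `model_parameters` object.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.data.frame(params),
            all(c("name", "value", "free", "lower", "upper") %in% names(params)))
  if (nrow(params) != 40)
    stop_hemofit("expected 40 parameters, got %d", nrow(params))
  if (sum(params$free) != 23)
    stop_hemofit("expected 23 subject-specific parameters, got %d", sum(params$free))
  v <- parameter_values(params)
  pos <- c("r_mv", "r_ao", "r_per", "r_pul", "r_ven", "c_aa", "c_per", "c_pul",
           "l_mv", "l_ao", "r_closed", "t_cycle", "rho", "dp_width")
  if (any(v[pos] <= 0))
    stop_hemofit("non-positive parameter(s): %s",
                 paste(pos[v[pos] <= 0], collapse = ", "))
  if (!(v["eoa"] > 0 && v["eoa"] < v["a_lvot"]))
    stop_hemofit("EOA (%g) must satisfy 0 < EOA < A_LVOT (%g)", v["eoa"], v["a_lvot"])
  for (ch in c("lv", "la")) {
    if (v[paste0(ch, "_emax")] <= v[paste0(ch, "_emin")])
      stop_hemofit("%s_emax must exceed %s_emin", ch, ch)
    if (v[paste0(ch, "_tmax")] <= 0 || v[paste0(ch, "_tmax")] >= v["t_cycle"])
      stop_hemofit("%s_tmax must lie inside the cycle", ch)
  }
  free <- params[params$free, ]
  bad <- free$value < free$lower | free$value > free$upper
  if (any(bad))
    stop_hemofit("free parameter(s) outside bounds: %s",
                 paste(free$name[bad], collapse = ", "))
  invisible(params)
}

#' Extract one elastance block
#'
#' @param params a `model_parameters` object.
#' @param chamber `"lv"` or `"la"`.
#' @return an [elastance_params()] object.
#' @export
chamber_elastance <- function(params, chamber = c("lv", "la")) {
  chamber <- match.arg(chamber)
  v <- parameter_values(params)
  g <- function(s) unname(v[paste0(chamber, "_", s)])
  elastance_params(e_max = g("emax"), e_min = g("emin"), r_c = g("rc"),
                   r_r = g("rr"), alpha_s = g("alpha_s"), alpha_d = g("alpha_d"),
                   t_max = g("tmax"), v0 = g("v0"),
                   T_cycle = unname(v["t_cycle"]))
}

#' Rescale a parameter set to a new cycle length
#'
#' Sets `t_cycle` and scales the absolute timing parameters (`lv_tmax`,
#' `la_tmax`, `la_onset`) proportionally, so the relative timing of systole and
#' the atrial kick is preserved when the heart rate changes between occasions.
#' The time-constant fractions `alpha_s`/`alpha_d` scale implicitly.
#'
#' @param params a `model_parameters` object.
#' @param T_new new cycle length (s).
#' @return the rescaled `model_parameters` object.
#' @export
rescale_cycle <- function(params, T_new) {
  v <- parameter_values(params)
  f <- T_new / unname(v["t_cycle"])
  set_parameters(params, c(t_cycle = T_new,
                           lv_tmax = unname(v["lv_tmax"]) * f,
                           la_tmax = unname(v["la_tmax"]) * f,
                           la_onset = unname(v["la_onset"]) * f))
}

#' Write / read a parameter set as JSON
#'
#' Flat `name -> {value, free, lower, upper}` mapping, UTF-8.
#'
#' @param params a `model_parameters` object.
#' @param path file path.
#' @return `read_parameters_json` returns the `model_parameters` object;
#'   the writer returns `path` invisibly.
#' @export
write_parameters_json <- function(params, path) {
  obj <- lapply(seq_len(nrow(params)), function(i)
    list(value = params$value[i], free = params$free[i],
         lower = params$lower[i], upper = params$upper[i]))
  names(obj) <- params$name
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  tab <- data.frame(name  = names(obj),
                    value = vapply(obj, function(x) as.numeric(x$value), 0),
                    free  = vapply(obj, function(x) isTRUE(x$free), TRUE),
                    lower = vapply(obj, function(x) as.numeric(x$lower), 0),
                    upper = vapply(obj, function(x) as.numeric(x$upper), 0),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  # canonical ordering: results must not depend on file ordering
  tab <- tab[match(.PARAM_TABLE()$name, tab$name), ]
  if (any(is.na(tab$name))) stop_hemofit("parameter file is missing entries")
  rownames(tab) <- NULL
  class(tab) <- c("model_parameters", "data.frame")
  validate_parameters(tab)
  tab
}

#' Energy-loss coefficient of the aortic valve
#'
#' `ELCo = EOA * A_LVOT / (A_LVOT - EOA)` (cm^2), the effective area governing
#' the net transvalvular pressure loss.
#'
#' @param eoa effective orifice area (cm^2).
#' @param a_lvot outflow-tract cross-sectional area (cm^2).
#' @return ELCo in cm^2.
#' @examples
#' derive_elco(3, 4)        # 12
#' derive_elco(2, 4)        # == a_lvot when eoa = a_lvot/2
#' @export
derive_elco <- function(eoa, a_lvot) {
  if (any(eoa <= 0)) stop_hemofit("EOA must be positive")
  if (any(eoa >= a_lvot))
    stop_hemofit("valve area exceeds outflow tract (EOA = %g, A_LVOT = %g)",
                 max(eoa), min(a_lvot))
  eoa * a_lvot / (a_lvot - eoa)
}
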