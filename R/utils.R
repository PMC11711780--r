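# Package-wide unit conventions: volumes in mL, time in s, pressures in mmHg,
# areas in cm^2, flows in mL/s, density in g/mL.

# Conversion applied to the convective valve term: dyn-cm-s pressure times
# (0.06/133.322) yields mmHg as printed in the source formulation. Kept as a
# single centralized constant.
.PG_UNIT <- 0.06 / 133.322

#' Trapezoidal integral of a sampled trace
#'
#' Thin wrapper around [pracma::trapz()] so every quadrature in the package
#' goes through one rule.
#'
#' @param t sample times (s), strictly increasing.
#' @param y sampled values.
#' @return the trapezoidal integral.
#' @keywords internal
trapz_ <- function(t, y) pracma::trapz(t, y)

#' Periodic linear interpolation
#'
#' Interpolates a periodic trace sampled on `[0, T)` at arbitrary query times,
#' wrapping both the query times and the closing sample of the cycle.
#'
#' @param t sample times in `[0, T)`.
#' @param y values at `t`.
#' @param T_cycle cycle length (s).
#' @param tq query times (any real values; reduced modulo `T_cycle`).
#' @return interpolated values at `tq`.
#' @keywords internal
periodic_interp <- function(t, y, T_cycle, tq) {
  stopifnot(length(t) == length(y), T_cycle > 0)
  tq <- tq %% T_cycle
  # close the cycle: value at T equals value at 0
  keep <- t < T_cycle - 1e-12
  tt <- c(t[keep], t[1] + T_cycle)
  yy <- c(y[keep], y[1])
  stats::approx(tt, yy, xout = tq, rule = 2)$y
}

#' Uniform time grid over one cycle
#'
#' @param T_cycle cycle length (s).
#' @param dt sampling interval (s).
#' @return times `0, dt, 2 dt, ...` strictly below `T_cycle`.
#' @keywords internal
cycle_grid <- function(T_cycle, dt) seq(0, T_cycle - dt / 2, by = dt)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hemofit <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
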