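# Independent brute-force oracles, deliberately written differently from the
# package implementations they are checked against.

# direct-formula Bland-Altman
oracle_bland_altman <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  c(bias = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
}

# direct-formula repeatability CoV (RMS within-subject SD over grand mean)
oracle_cov <- function(a, b) {
  within_var <- (a - b)^2 / 2
  100 * sqrt(sum(within_var) / length(within_var)) / mean(c(a, b))
}

# exact two-sided rank-sum p by explicit enumeration over index subsets
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  n_a <- length(a)
  idx <- utils::combn(length(x), n_a)
  sums <- apply(idx, 2, function(j) sum(r[j]))
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (length(x) + 1) / 2
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

# RMSE by explicit loop on a shared phase grid
oracle_rmse <- function(ta, qa, Ta, tb, qb, Tb, n) {
  interp_periodic <- function(tt, qq, Tc, ph) {
    tt <- c(tt, tt[1] + Tc)
    qq <- c(qq, qq[1])
    vapply(ph * Tc, function(x) {
      i <- findInterval(x, tt)
      i <- max(min(i, length(tt) - 1), 1)
      qq[i] + (qq[i + 1] - qq[i]) * (x - tt[i]) / (tt[i + 1] - tt[i])
    }, 0)
  }
  ph <- seq(0, 1 - 1 / n, length.out = n)
  ya <- interp_periodic(ta / Ta, qa, 1, ph)
  yb <- interp_periodic(tb / Tb, qb, 1, ph)
  sqrt(sum((ya - yb)^2) / n)
}

# closed-cycle trapezoid by explicit summation
oracle_net_flow <- function(t, q, Tc) {
  tt <- c(t, t[1] + Tc)
  qq <- c(q, q[1])
  s <- 0
  for (i in seq_len(length(tt) - 1))
    s <- s + (tt[i + 1] - tt[i]) * (qq[i] + qq[i + 1]) / 2
  s
}

# dense-grid activation oracle: shape evaluated on 1e5 points
oracle_activation_grid <- function(r_c, r_r, alpha_s, alpha_d, T_cycle,
                                   n = 1e5) {
  t <- seq(1e-9, T_cycle, length.out = n)
  xs <- (t / (alpha_s * T_cycle))^r_c
  xd <- (t / (alpha_d * T_cycle))^r_r
  h <- xs / (1 + xs) / (1 + xd)
  list(t = t, h = h, t_peak = t[which.max(h)], h_peak = max(h))
}

# helper constructors for compact tests
make_waveform <- function(fun, T_cycle = 1, n = 50,
                          site = "aortic_valve") {
  t <- seq(0, T_cycle * (1 - 1 / n), length.out = n)
  flow_waveform(site, t, fun(t), T_cycle)
}

half_sine <- function(A, width) function(t) ifelse(t < width,
                                                   A * sin(pi * t / width), 0)

# quick converged default simulation shared across tests
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_model(default_parameters())
    cache
  }
})
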