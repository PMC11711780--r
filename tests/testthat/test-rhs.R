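test_that("compiled and reference right-hand sides agree at random states", {
  set.seed(3)
  p <- default_parameters()
  v <- parameter_values(p)
  for (i in 1:20) {
    st <- c(v_lv = runif(1, 40, 140), v_la = runif(1, 20, 80),
            v_aa = runif(1, 58, 75), v_per = runif(1, 650, 760),
            v_pul = runif(1, 250, 350), q_mv = runif(1, -5, 400),
            q_av = runif(1, -5, 600), q_ao = runif(1, -20, 400))
    t <- runif(1, 0, 1)
    d_r <- ode_rhs(t, st, v)[[1]]
    sim <- deSolve::lsoda(st, c(t, t + 1e-9), func = "hemo_derivs",
                          parms = v, dllname = "hemofit",
                          initfunc = "hemo_initmod")
    # compare via a one-step integration proxy: evaluate C rhs directly
    d_c <- .C("hemo_derivs", as.integer(8), as.double(t), as.double(st),
              dstate = double(8), double(1), integer(1),
              PACKAGE = "hemofit")$dstate
    expect_equal(unname(d_c), unname(d_r), tolerance = 1e-12)
  }
})

test_that("total blood volume is conserved by construction", {
  set.seed(4)
  v <- parameter_values(default_parameters())
  for (i in 1:10) {
    st <- c(v_lv = runif(1, 40, 140), v_la = runif(1, 20, 80),
            v_aa = runif(1, 58, 75), v_per = runif(1, 650, 760),
            v_pul = runif(1, 250, 350), q_mv = runif(1, 0, 400),
            q_av = runif(1, 0, 600), q_ao = runif(1, 0, 400))
    d <- ode_rhs(runif(1, 0, 1), st, v)[[1]]
    expect_equal(sum(d[1:5]), 0, tolerance = 1e-10)
  }
})

test_that("all-equal pressures with closed valves give a zero derivative", {
  p <- default_parameters()
  v <- parameter_values(p)
  # late diastole, both chambers passive; choose volumes so every pressure
  # equals the reservoir operating pressure
  t <- 0.999 * v[["t_cycle"]]
  e_lv <- elastance(t, chamber_elastance(p, "lv"), v[["t_cycle"]])
  e_la <- elastance((t - v[["la_onset"]]) %% v[["t_cycle"]],
                    chamber_elastance(p, "la"), v[["t_cycle"]])
  P <- v[["p_pul0"]]
  st <- c(v_lv = v[["lv_v0"]] + P / e_lv, v_la = v[["la_v0"]] + P / e_la,
          v_aa = v[["aa_v0"]] + P * v[["c_aa"]],
          v_per = v[["per_v0"]] + P * v[["c_per"]],
          v_pul = v[["v_pul0"]], q_mv = 0, q_av = 0, q_ao = 0)
  d <- ode_rhs(t, st, v)[[1]]
  expect_equal(unname(d), rep(0, 8), tolerance = 1e-9)
})

test_that("a one-compartment RC reduction matches the closed-form decay", {
  # compliance C draining through resistance R to a zero-pressure sink,
  # using the same pressure law and solver settings as the full model
  C <- 1.7; R <- 1.0; v0 <- 550; V0 <- v0 + 100 * C
  rhs <- function(t, y, parms) list(-((y - v0) / C) / R)
  out <- deSolve::lsoda(c(v = V0), seq(0, 3, by = 0.1), rhs, parms = NULL,
                        rtol = 1e-6, atol = 1e-8)
  exact <- v0 + (V0 - v0) * exp(-out[, 1] / (R * C))
  expect_lt(max(abs(out[, 2] - exact) / (exact - v0 + 1e-9)), 1e-3)
})

test_that("non-finite states are rejected with the failure time", {
  v <- parameter_values(default_parameters())
  st <- c(v_lv = NaN, v_la = 50, v_aa = 60, v_per = 700, v_pul = 300,
          q_mv = 0, q_av = 0, q_ao = 0)
  expect_error(ode_rhs(0.25, st, v), "non-finite state at t = 0.25")
})
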