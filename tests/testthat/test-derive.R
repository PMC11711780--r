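test_that("EOA from a rectangular pulse is the flow-to-velocity ratio", {
  n <- 100
  t <- seq(0, 0.99, length.out = n)
  q <- ifelse(t >= 0.2 & t <= 0.5, 300, 0)
  v <- ifelse(t >= 0.2 & t <= 0.5, 100, 0)
  w <- flow_waveform("aortic_valve", t, q, 1)
  vt <- velocity_trace(t, v)
  # both integrals share the same support, so the ratio is exactly 300/100
  expect_equal(derive_eoa(w, vt), 3)
  # homogeneity: doubling the velocity halves the EOA
  expect_equal(derive_eoa(w, velocity_trace(t, 2 * v)), 1.5)
})

test_that("EOA from half-sine pulses matches the analytic ratio", {
  n <- 400
  t <- seq(0, 1 - 1 / n, length.out = n)
  q <- half_sine(400, 0.3)(t)
  v <- half_sine(120, 0.3)(t)
  w <- flow_waveform("aortic_valve", t, q, 1)
  # analytic: SV = 2*400*0.3/pi, VTI = 2*120*0.3/pi -> EOA = 400/120
  expect_equal(derive_eoa(w, velocity_trace(t, v)), 400 / 120,
               tolerance = 1e-3)
  expect_equal(net_flow(w), 2 * 400 * 0.3 / pi, tolerance = 1e-3)
})

test_that("EOA derivation converges under grid refinement", {
  vals <- vapply(c(50, 200, 800), function(n) {
    t <- seq(0, 1 - 1 / n, length.out = n)
    derive_eoa(flow_waveform("aortic_valve", t, half_sine(400, 0.3)(t), 1),
               velocity_trace(t, half_sine(120, 0.3)(t)))
  }, 0)
  err <- abs(vals - 400 / 120)
  expect_true(all(diff(err) <= 1e-9))  # error shrinks with refinement
  expect_lt(err[3], 1e-4)
})

test_that("EOA derivation rejects bad inputs", {
  n <- 40
  t <- seq(0, 0.975, length.out = n)
  w <- flow_waveform("aortic_valve", t, half_sine(400, 0.3)(t), 1)
  expect_error(derive_eoa(w, velocity_trace(t, -half_sine(120, 0.3)(t))),
               "VTI")
  expect_error(derive_eoa(w, velocity_trace(t + 0.002,
                                            half_sine(120, 0.3)(t))),
               "grid")
  w_mv <- flow_waveform("mitral_valve", t, half_sine(400, 0.3)(t), 1)
  expect_error(derive_eoa(w_mv, velocity_trace(t, half_sine(120, 0.3)(t))),
               "aortic")
})

make_bundle <- function(sbp = 120, dbp = 75, esv = 50, eoa = 3, a_lvot = 4,
                        peak_q = 400) {
  n <- 40
  t <- seq(0, 0.975, length.out = n)
  q <- half_sine(peak_q, 0.3)(t)
  waves <- list(
    mitral_valve = flow_waveform("mitral_valve", t, half_sine(300, 0.4)(t), 1),
    aortic_valve = flow_waveform("aortic_valve", t, q, 1),
    ascending_aorta = flow_waveform("ascending_aorta", t, q, 1))
  measurement_bundle("S1", "observer1_a", 1, esv, eoa, a_lvot, sbp, dbp,
                     waves)
}

test_that("single-beat maximal elastance matches the worked example", {
  b <- make_bundle()
  pg <- 1.06 / (2 * 12^2) * 400^2 * (0.06 / 133.322)
  expect_equal(derive_emax_lv(b, v0_lv = 10), 0.9 * (120 + pg) / 40)
  expect_equal(derive_emax_lv(b, v0_lv = 10), 2.706, tolerance = 1e-3)
})

test_that("maximal elastance limits and monotonicity behave as expected", {
  # zero-flow limit: convective gradient vanishes
  b0 <- make_bundle(sbp = 100, esv = 60, peak_q = 1e-6)
  expect_equal(derive_emax_lv(b0, v0_lv = 10), 0.9 * 100 / 50,
               tolerance = 1e-9)
  # doubling (ESV - V0) halves E_max at fixed numerator
  b1 <- make_bundle(esv = 30); b2 <- make_bundle(esv = 50)
  expect_equal(derive_emax_lv(b1, v0_lv = 10) / 2,
               derive_emax_lv(b2, v0_lv = 10))
  # monotone: increasing SBP increases E_max; increasing ESV decreases it
  expect_gt(derive_emax_lv(make_bundle(sbp = 130), 10),
            derive_emax_lv(make_bundle(sbp = 120), 10))
  expect_lt(derive_emax_lv(make_bundle(esv = 60), 10),
            derive_emax_lv(make_bundle(esv = 50), 10))
  expect_error(derive_emax_lv(make_bundle(esv = 9), 10), "exceed")
})

test_that("assembled parameters honor the measurement-derived windows", {
  b <- make_bundle(eoa = 3.0, a_lvot = 4.0)
  p <- assemble_parameters(b)
  expect_identical(sum(p$free), 23L)
  g <- function(nm, col) p[[col]][match(nm, p$name)]
  expect_equal(g("eoa", "value"), 3.0)
  expect_equal(g("eoa", "lower"), 2.7)
  expect_equal(g("eoa", "upper"), 3.3)
  expect_equal(g("a_lvot", "lower"), 0.9 * 4)
  expect_equal(g("lv_emax", "value"), derive_emax_lv(b, 10))
  expect_equal(g("t_cycle", "value"), 1)
  expect_false(p$free[match("t_cycle", p$name)])
  # fixed parameters other than the measured cycle length stay at defaults
  d <- default_parameters()
  fixed <- setdiff(d$name[!d$free], "t_cycle")
  expect_identical(p$value[match(fixed, p$name)],
                   d$value[match(fixed, d$name)])
  # purity: assembling again gives the identical object
  expect_identical(assemble_parameters(b), p)
})
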