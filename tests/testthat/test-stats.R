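test_that("Bland-Altman matches the hand-worked example and the oracle", {
  ps <- paired_series("x", "-", c(1, 2, 3), c(2, 2, 5))
  ba <- bland_altman(ps)
  expect_equal(ba$bias, -1)
  expect_equal(ba$loa_low, -2.96)
  expect_equal(ba$loa_high, 0.96)
  # identical occasions: zero bias, degenerate limits
  ba0 <- bland_altman(paired_series("x", "-", c(1, 2, 3), c(1, 2, 3)))
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # swapping sides negates the bias and mirrors the limits
  ba_sw <- bland_altman(paired_series("x", "-", c(2, 2, 5), c(1, 2, 3)))
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$loa_low, -ba$loa_high)
  expect_error(paired_series("x", "-", 1, 2), "pairs")
})

test_that("repeatability CoV matches the worked example and is scale-free", {
  ps <- paired_series("x", "-", c(10, 20), c(12, 20))
  expect_equal(cov_repeatability(ps), 100 * 1 / 15.5)
  expect_equal(cov_repeatability(paired_series("x", "-", c(5, 7), c(5, 7))),
               0)
  ps_scaled <- paired_series("x", "-", 3.7 * c(10, 20), 3.7 * c(12, 20))
  expect_equal(cov_repeatability(ps_scaled), cov_repeatability(ps))
  expect_error(cov_repeatability(paired_series("x", "-", c(-10, 10),
                                               c(-10, 10))), "grand mean")
})

test_that("statistics match brute-force oracles on random small inputs", {
  set.seed(21)
  for (i in 1:120) {
    n <- sample(3:10, 1)
    a <- round(rnorm(n, 50, 10), 1)
    b <- round(a + rnorm(n, 0, 4), 1)
    ps <- paired_series("x", "-", a, b)
    ba <- bland_altman(ps)
    o <- oracle_bland_altman(a, b)
    expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), unname(o))
    expect_equal(cov_repeatability(ps), oracle_cov(a, b))
    expect_equal(rank_test(ps)$p_value, oracle_ranksum_p(a, b))
  }
})

test_that("exact rank-sum enumerates the extreme-separation example", {
  r <- rank_test(a = c(1, 2, 3), b = c(10, 11, 12))
  expect_equal(r$p_value, 2 / 20)  # 2 extreme of C(6,3) = 20 assignments
  expect_identical(r$method, "exact enumeration")
  # identical samples: p = 1
  expect_equal(rank_test(a = c(1, 2, 3), b = c(1, 2, 3))$p_value, 1)
  # shift invariance of ranks
  expect_equal(rank_test(a = c(1, 5, 7, 2), b = c(3, 4, 8, 9))$p_value,
               rank_test(a = c(1, 5, 7, 2) + 100,
                         b = c(3, 4, 8, 9) + 100)$p_value)
  # fully tied data is flagged degenerate
  d <- rank_test(a = c(2, 2, 2), b = c(2, 2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("large-sample rank-sum matches the base-R normal approximation", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(11, 0.4)
    ours <- rank_test(a = a, b = b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_identical(ours$method, "normal approximation")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("net flow matches closed forms on canonical waveforms", {
  n <- 50
  t <- seq(0, 1 - 1 / n, length.out = n)
  w_const <- flow_waveform("mitral_valve", t, rep(100, n), 1)
  expect_equal(net_flow(w_const), 100)  # closed-cycle integral
  w_anti <- flow_waveform("mitral_valve", t, sin(2 * pi * t), 1)
  expect_equal(net_flow(w_anti), 0, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:30) {
    q <- rnorm(n, 50, 30)
    w <- flow_waveform("mitral_valve", t, q, 1)
    expect_equal(net_flow(w), oracle_net_flow(t, q, 1))
  }
})

test_that("waveform RMSE matches closed forms and the oracle", {
  n <- 60
  t <- seq(0, 1 - 1 / n, length.out = n)
  a <- flow_waveform("aortic_valve", t, half_sine(300, 0.3)(t), 1)
  expect_equal(waveform_rmse(a, a), 0)
  b <- flow_waveform("aortic_valve", t, half_sine(300, 0.3)(t) + 25, 1)
  expect_equal(waveform_rmse(a, b), 25, tolerance = 1e-9)
  zero <- flow_waveform("aortic_valve", t, rep(0, n), 1)
  # half-sine of amplitude A over fraction f: RMSE = A sqrt(f/2)
  expect_equal(waveform_rmse(a, zero), 300 * sqrt(0.3 / 2), tolerance = 5e-3)
  expect_error(waveform_rmse(a, flow_waveform("mitral_valve", t,
                                              half_sine(300, 0.3)(t), 1)),
               "site")
  # different cycle lengths are aligned on cycle fraction
  t2 <- seq(0, 0.8 - 0.8 / n, length.out = n)
  a2 <- flow_waveform("aortic_valve", t2, half_sine(300, 0.24)(t2), 0.8)
  expect_equal(waveform_rmse(a, a2), 0, tolerance = 2)
  set.seed(14)
  for (i in 1:20) {
    qa <- rnorm(n, 0, 50); qb <- rnorm(n, 0, 50)
    wa <- flow_waveform("aortic_valve", t, qa, 1)
    wb <- flow_waveform("aortic_valve", t, qb, 1)
    expect_equal(waveform_rmse(wa, wb), oracle_rmse(t, qa, 1, t, qb, 1, n))
  }
})

test_that("limits of agreement scale linearly, CoV stays invariant", {
  set.seed(15)
  a <- rnorm(8, 50, 5); b <- a + rnorm(8, 0, 2)
  for (c_ in c(0.5, 3)) {
    ba <- bland_altman(paired_series("x", "-", a, b))
    ba_c <- bland_altman(paired_series("x", "-", c_ * a, c_ * b))
    expect_equal(ba_c$bias, c_ * ba$bias)
    expect_equal(ba_c$loa_high, c_ * ba$loa_high)
    expect_equal(cov_repeatability(paired_series("x", "-", c_ * a, c_ * b)),
                 cov_repeatability(paired_series("x", "-", a, b)))
  }
})

test_that("the variability study assembles one row per tracked quantity", {
  zero <- noise_model()
  design <- list(observer1_a = zero, observer1_b = zero)
  co <- build_cohort(n_subjects = 3, seed = 4, design = design)
  rep <- run_variability_study(co, "intra")
  expect_identical(nrow(rep$table), 4L)  # A_LVOT, ESV, EOA, T
  expect_true(all(abs(rep$table$bias) < 1e-9))
  expect_true(all(rep$table$cov_percent < 1e-9))
  expect_true(all(rep$rmse$rmse < 1e-9))
  expect_identical(nrow(rep$rmse), 9L)   # 3 sites x 3 subjects
  # rerunning is a pure function of the cohort
  expect_identical(run_variability_study(co, "intra"), rep)
  expect_error(run_variability_study(co, "sequence"), "sgre")
})

test_that("report gains the seven model parameters when estimates are given", {
  zero <- noise_model()
  design <- list(observer1_a = zero, observer1_b = zero)
  co <- build_cohort(n_subjects = 2, seed = 4, design = design)
  # stand-in estimates: the truth itself (estimation tested elsewhere)
  est <- list(observer1_a = lapply(co$subjects, function(s)
                structure(list(params = s$truth), class = "estimation_result")),
              observer1_b = lapply(co$subjects, function(s)
                structure(list(params = s$truth), class = "estimation_result")))
  rep <- run_variability_study(co, "intra", estimates = est)
  expect_identical(nrow(rep$table), 11L)  # 4 inputs + 7 parameters
  expect_true(all(rep$table$loa_low <= rep$table$bias + 1e-12))
  expect_true(all(rep$table$bias <= rep$table$loa_high + 1e-12))
})
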