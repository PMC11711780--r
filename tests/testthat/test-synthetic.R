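test_that("subject draws are reproducible and converge", {
  s1 <- draw_subject(seed = 5)
  s2 <- draw_subject(seed = 5)
  expect_identical(s1$value, s2$value)
  expect_false(identical(draw_subject(seed = 6)$value, s1$value))
  # collapsed ranges give a deterministic subject at that point
  pt <- lapply(subject_ranges(), function(r) rep(mean(r), 2))
  d1 <- draw_subject(seed = 1, ranges = pt)
  d2 <- draw_subject(seed = 99, ranges = pt)
  expect_identical(d1$value, d2$value)
  # a handful of default-range draws all converge
  for (i in 1:5) {
    sim <- simulate_model(draw_subject(seed = 300 + i))
    expect_true(sim$converged)
    expect_true(all(sim$v_lv > 0))
  }
})

test_that("draw ranges outside the parameter bounds are rejected", {
  expect_error(draw_subject(seed = 1, ranges = list(c_aa = c(0.001, 0.01))),
               "c_aa")
})

test_that("zero-noise observation reproduces the derivable truth exactly", {
  truth <- default_parameters()
  sim <- simulate_model(truth)
  b <- observe(truth, noise_model(), seed = 3, sim = sim)
  v <- parameter_values(truth)
  expect_identical(b$eoa, unname(v["eoa"]))
  expect_identical(b$a_lvot, unname(v["a_lvot"]))
  expect_identical(b$esv, min(sim$v_lv))
  expect_identical(b$sbp, max(sim$p_aa))
  expect_identical(b$T_cycle, unname(v["t_cycle"]))
  # waveform equals the resampled simulation (no noise)
  w <- sim_waveform(sim, "aortic_valve", dt = 0.04)
  expect_equal(b$waveforms$aortic_valve$flow, w$flow)
})

test_that("observer noise levels order intra below inter by construction", {
  truth <- default_parameters()
  sim <- simulate_model(truth)
  v <- parameter_values(truth)
  set.seed(42)
  dev <- sapply(c("observer1_b", "observer2"), function(occ) {
    nm <- study_noise_model(occ)
    mean(replicate(40, {
      b <- observe(truth, nm, seed = sample.int(1e6, 1), occasion = occ,
                   sim = sim)
      abs(b$a_lvot - v[["a_lvot"]]) / v[["a_lvot"]]
    }))
  })
  expect_gt(dev[["observer2"]], dev[["observer1_b"]])
})

test_that("heart-rate variation re-simulates the physiology at the new T", {
  truth <- default_parameters()
  b <- observe(truth, study_noise_model("epi"), seed = 11)
  expect_false(identical(b$T_cycle,
                         parameter_values(truth)[["t_cycle"]]))
  expect_equal(b$waveforms$mitral_valve$T_cycle, b$T_cycle)
  # 30 ms resampling for the epi-like occasion
  expect_equal(diff(b$waveforms$mitral_valve$time)[1], 0.03)
})

test_that("resampling alone produces small but nonzero waveform differences", {
  truth <- default_parameters()
  sim <- simulate_model(truth)
  b40 <- observe(truth, noise_model(dt = 0.04), seed = 1, sim = sim)
  b30 <- observe(truth, noise_model(dt = 0.03), seed = 1, sim = sim)
  r <- waveform_rmse(b40$waveforms$aortic_valve, b30$waveforms$aortic_valve)
  expect_gt(r, 0)
  expect_lt(r, 0.05 * max(b40$waveforms$aortic_valve$flow))
})

test_that("cohorts cover the five-occasion design reproducibly", {
  co <- build_cohort(n_subjects = 2, seed = 9)
  expect_length(co$subjects, 2)
  expect_identical(names(co$subjects[[1]]$bundles),
                   c("observer1_a", "observer1_b", "observer2", "sgre",
                     "epi"))
  co2 <- build_cohort(n_subjects = 2, seed = 9)
  expect_identical(co$subjects[[2]]$bundles$epi$waveforms$mitral_valve$flow,
                   co2$subjects[[2]]$bundles$epi$waveforms$mitral_valve$flow)
  # the two sequence occasions share the one morphological ESV analysis
  expect_identical(co$subjects[[1]]$bundles$sgre$esv,
                   co$subjects[[1]]$bundles$epi$esv)
})

test_that("a zero-noise design makes all observer occasions identical", {
  zero <- noise_model()
  design <- list(observer1_a = zero, observer1_b = zero, observer2 = zero)
  co <- build_cohort(n_subjects = 1, seed = 2, design = design)
  b <- co$subjects[[1]]$bundles
  expect_identical(b$observer1_a$esv, b$observer1_b$esv)
  expect_identical(b$observer1_a$waveforms$aortic_valve$flow,
                   b$observer2$waveforms$aortic_valve$flow)
})

test_that("paired scalar noise calibrates to the prescribed CoVs", {
  truth <- default_parameters()
  sim <- simulate_model(truth)
  nm_a <- study_noise_model("observer1_a")
  nm_b <- study_noise_model("observer1_b")
  n <- 300
  a <- t(vapply(1:n, function(i) {
    b <- observe(truth, nm_a, seed = 2 * i, sim = sim)
    c(b$a_lvot, b$esv, b$eoa)
  }, numeric(3)))
  b <- t(vapply(1:n, function(i) {
    bb <- observe(truth, nm_b, seed = 2 * i + 1, sim = sim)
    c(bb$a_lvot, bb$esv, bb$eoa)
  }, numeric(3)))
  target <- c(a_lvot = 2.8, esv = 3.0, eoa = 1.5)
  for (j in 1:3) {
    emp <- oracle_cov(a[, j], b[, j])
    expect_lt(abs(emp - target[j]) / target[j], 0.15)
  }
})
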