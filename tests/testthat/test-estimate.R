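# bundle generated by the model itself, on the simulation's own grid
self_bundle <- function(params, dt = 0.04) {
  sim <- simulate_model(params)
  observe(params, noise_model(dt = dt), seed = 1, sim = sim)
}

test_that("cost vanishes for a bundle generated by the same parameters", {
  p <- default_parameters()
  b <- self_bundle(p)
  cb <- cost(p, b)
  # residual discretization + periodicity truncation only
  expect_lt(sum(cb$components[c("mitral_valve", "aortic_valve",
                                "ascending_aorta")]), 1e-4)
  expect_lt(abs(cb$sbp_residual), 0.5)
  expect_lt(abs(cb$dbp_residual), 0.5)
})

test_that("cost is linear in the weights and zero when weights vanish", {
  p <- default_parameters(c_aa = 0.1)
  b <- self_bundle(default_parameters())
  w0 <- default_weights()
  w0$flow[] <- 0; w0$pressure <- 0
  expect_equal(cost(p, b, w0)$total, 0)
  w1 <- default_weights()
  w2 <- default_weights(); w2$flow["mitral_valve"] <- 2
  c1 <- cost(p, b, w1); c2 <- cost(p, b, w2)
  expect_equal(c2$total - c1$total, c1$components[["mitral_valve"]])
})

test_that("an unsimulatable parameter set yields an infinite-cost sentinel", {
  p <- default_parameters()
  p$value[p$name == "l_mv"] <- 1e-300   # degenerate inertance
  b <- self_bundle(default_parameters())
  cb <- suppressWarnings(cost(p, b))
  expect_identical(cb$total, Inf)
  expect_true(nzchar(cb$message))
})

test_that("estimation is deterministic under a fixed seed", {
  b <- self_bundle(default_parameters())
  e1 <- estimate(b, seed = 7, n_starts = 2, maxiter = 3,
                 restart_threshold = 0)
  e2 <- estimate(b, seed = 7, n_starts = 2, maxiter = 3,
                 restart_threshold = 0)
  expect_identical(e1$params$value, e2$params$value)
  expect_identical(e1$start_costs, e2$start_costs)
})

test_that("the measured cycle length is never optimized", {
  truth <- default_parameters()
  b1 <- self_bundle(truth)
  p1 <- rescale_cycle(truth, 0.9)
  b2 <- self_bundle(p1)
  e <- estimate(b2, seed = 1, n_starts = 1, maxiter = 2)
  expect_identical(parameter_values(e$params)[["t_cycle"]], b2$T_cycle)
  expect_false(identical(b1$T_cycle, b2$T_cycle))
})

test_that("fitted values respect bounds and cost does not exceed the start", {
  truth <- draw_subject(seed = 31)
  b <- observe(truth, noise_model(), seed = 32)
  e <- estimate(b, seed = 1, n_starts = 1, maxiter = 25)
  start <- assemble_parameters(b)
  expect_true(all(e$params$value[e$params$free] >=
                    e$params$lower[e$params$free] - 1e-12))
  expect_true(all(e$params$value[e$params$free] <=
                    e$params$upper[e$params$free] + 1e-12))
  expect_lte(e$cost$total, cost(start, b)$total + 1e-12)
  # the derived inputs stay inside their +/- 10% windows
  for (nm in c("eoa", "a_lvot", "lv_emax")) {
    i <- match(nm, start$name)
    expect_gte(e$params$value[i], 0.9 * start$value[i] - 1e-9)
    expect_lte(e$params$value[i], 1.1 * start$value[i] + 1e-9)
  }
})

test_that("noise-free recovery finds the generating parameters (smoke)", {
  truth <- draw_subject(seed = 101)
  b <- observe(truth, noise_model(), seed = 201)
  e <- estimate(b, seed = 1, n_starts = 1, maxiter = 100,
                periodicity_tol = 1e-4)
  hn <- c("lv_emin", "lv_emax", "lv_rc", "lv_rr", "lv_alpha_s",
          "lv_alpha_d", "c_aa")
  err <- abs(parameter_values(e$params)[hn] - parameter_values(truth)[hn]) /
    abs(parameter_values(truth)[hn])
  expect_lt(median(err), 0.05)
})
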