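test_that("noiseless ROI-average fit recovers the generating parameters", {
  truth <- fix_params()
  sim <- simulate_placentome(list(truth), array(1L, c(4, 4, 1)))
  fit <- fit_decide_roi(sim$series)
  expect_true(fit$converged)
  est <- unlist(fit$params)
  expect_equal(est, unlist(truth)[names(est)], tolerance = 1e-3)
  # far tighter than the 0.1% contract in practice
  expect_lt(max(abs(est - unlist(truth)[names(est)]) /
                  unlist(truth)[names(est)]), 1e-6)
})

test_that("noiseless fit objective at the solution is at most that at truth", {
  # 12-point grid: the constrained optimum can only improve on the truth
  g <- acquisition_grid(rep(c(0, 100, 400), 4),
                        rep(c(72, 96, 144, 192), each = 3))
  truth <- fix_params()
  sim <- simulate_placentome(list(truth), array(1L, c(3, 3, 1)), grid = g)
  fit <- fit_decide_roi(sim$series)
  expect_lt(fit$residual_norm, 1e-8)   # truth attains 0; solver matches it
})

test_that("multi-start agreement: random feasible starts reach one solution", {
  truth <- fix_params()
  sim <- simulate_placentome(list(truth), array(1L, c(4, 4, 1)))
  set.seed(7)
  ests <- replicate(4, {
    init <- random_feasible_params()
    unlist(fit_decide_roi(sim$series, init = init)$params)
  })
  spread <- apply(ests, 1, function(x) diff(range(x)) / abs(mean(x)))
  expect_lt(max(spread), 1e-6)
})

test_that("flat signal curves are flagged degenerate, not fitted", {
  g <- default_grid()
  sig <- array(50, c(2, 2, 1, nrow(g)))
  ser <- placentome_series(sig, array(TRUE, c(2, 2, 1)), g)
  fit <- fit_decide_roi(ser)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
})

test_that("empty masks and non-identifiable grids are rejected", {
  g <- default_grid()
  sig <- array(1, c(2, 2, 1, nrow(g)))
  expect_error(fit_decide_roi(placentome_series(sig, array(FALSE, c(2, 2, 1)),
                                                g)), "empty mask")
  g1 <- acquisition_grid(c(0, 100, 200, 400, 600, 800), 80)
  sig1 <- array(1, c(2, 2, 1, 6))
  expect_error(fit_decide_roi(placentome_series(sig1, array(TRUE, c(2, 2, 1)),
                                                g1)), "non-identifiable")
})

test_that("voxelwise fit recovers a noiseless two-block phantom", {
  pA <- decide_params(f = 0.2, v = 0.35, d = 1.2e-3, d_star = 0.02,
                      T2fb = 80, S0 = 100)
  pB <- decide_params(f = 0.35, v = 0.2, d = 1.8e-3, d_star = 0.05,
                      T2fb = 60, S0 = 90)
  lab <- array(rep(c(1L, 2L), each = 50), c(10, 10, 1))
  sim <- simulate_placentome(list(pA, pB), lab)
  maps <- fit_decide_voxelwise(sim$series)
  for (nm in c("S0", "f", "v", "d", "d_star", "T2fb")) {
    rel <- abs(maps[[nm]] - sim$truth[[nm]]) / sim$truth[[nm]]
    expect_lt(max(rel, na.rm = TRUE), 0.005)
  }
  expect_true(all(maps$converged[lab > 0]))
  expect_true(all(is.na(maps$f[array(FALSE, dim(lab)) | lab == 0])))
})

test_that("fitted parameters never leave their boxes, even on pure noise", {
  g <- default_grid()
  set.seed(33)
  for (i in 1:25) {
    y <- abs(stats::rnorm(nrow(g), mean = 5, sd = 3)) + 0.1
    fit <- decidemri:::.fit_decide_curve(
      y, g, decide_constants(), decidemri:::.init_theta(NULL, max(y)),
      decide_fit_control())
    p <- fit$params
    expect_true(p$f > 0 && p$f < 1)
    expect_true(p$v > 0 && p$v < 1)
    expect_true(p$d > 0 && p$d < 1)
    expect_true(p$d_star > 0 && p$d_star < 1)
    expect_true(p$T2fb > 0 && p$T2fb < 150)
    expect_true(p$S0 > 0)
  }
})

test_that("the logit-transformed route agrees with the bounded fit", {
  truth <- fix_params()
  sim <- simulate_placentome(list(truth), array(1L, c(3, 3, 1)))
  f_box <- fit_decide_roi(sim$series)
  f_log <- fit_decide_roi(sim$series,
                          control = decide_fit_control(transform = "logit"))
  expect_equal(unlist(f_log$params), unlist(f_box$params), tolerance = 1e-4)
})
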