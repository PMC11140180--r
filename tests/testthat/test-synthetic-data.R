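test_that("noise-free simulation reproduces the forward model exactly", {
  truth <- fix_params()
  g <- default_grid()
  sim <- simulate_placentome(list(truth), array(1L, c(3, 2, 1)), g)
  expected <- decide_signal(truth, decide_constants(), g$b_s_per_mm2,
                            g$TE_ms)
  for (i in 1:3) for (j in 1:2)
    expect_equal(as.numeric(sim$series$signal[i, j, 1, ]), expected,
                 tolerance = 1e-14)
  expect_equal(sim$truth$f[1, 1, 1], truth$f)
})

test_that("simulations are reproducible under a fixed seed", {
  truth <- fix_params()
  lab <- array(1L, c(4, 4, 1))
  a <- simulate_placentome(list(truth), lab,
                           noise = noise_spec("rician", 30, seed = 99))
  b <- simulate_placentome(list(truth), lab,
                           noise = noise_spec("rician", 30, seed = 99))
  expect_identical(a$series$signal, b$series$signal)
  t1 <- simulate_t2prep(60, noise = noise_spec("gaussian", 50, seed = 5))
  t2 <- simulate_t2prep(60, noise = noise_spec("gaussian", 50, seed = 5))
  expect_identical(t1$signals, t2$signals)
  c1 <- simulate_cohort(cohort_design(), seed = 12)
  c2 <- simulate_cohort(cohort_design(), seed = 12)
  expect_identical(c1$truth, c2$truth)
})

test_that("empirical SNR matches the requested level", {
  truth <- fix_params()
  sim <- simulate_placentome(list(truth), array(1L, c(100, 100, 1)),
                             noise = noise_spec("rician", 50, seed = 9))
  ref <- sim$series$signal[, , , 1]      # b = 0, minimum TE volume
  snr_hat <- mean(ref) / stats::sd(ref)
  expect_lt(abs(snr_hat - 50) / 50, 0.05)
})

test_that("a non-identifiable grid warns but still generates", {
  g <- acquisition_grid(c(0, 100, 200, 400, 600, 800), 80)
  expect_warning(sim <- simulate_placentome(list(fix_params()),
                                            array(1L, c(2, 2, 1)), g),
                 "non-identifiable")
  expect_equal(dim(sim$series$signal)[4], 6)
})

test_that("T2-prep simulation is exact without noise", {
  tau <- c(32, 64, 96, 128, 160, 192)
  ser <- simulate_t2prep(70, S0 = 120)
  expect_equal(ser$signals, 120 * exp(-tau / 70), tolerance = 1e-14)
  fit <- fit_t2_decay(ser)
  expect_equal(fit$T2, 70, tolerance = 1e-8)
})

test_that("T2 fit recovery stays within 2% bias at SNR 100", {
  set.seed(11)
  t2s <- replicate(300, fit_t2_decay(
    simulate_t2prep(55, 100, noise = noise_spec("gaussian", 100)))$T2)
  expect_lt(abs(mean(t2s) - 55) / 55, 0.02)
})

test_that("plug-flow cine recovers the analytic flow exactly in-mask", {
  sim <- simulate_pc_cine("plug", vmax = 20, radius_mm = 5, venc = 100,
                          pixel_mm = 0.5, n_phases = 4)
  fl <- roi_flow(sim$series, sim$roi)
  # plug profile: measured flow = vmax * (#pixels * pixel area), and the
  # analytic value uses the exact disc area; both agree on the same mask
  expect_equal(fl$mean_flow, 20 * sum(sim$roi) * sim$pixel_area * 60,
               tolerance = 1e-12)
  expect_equal(sim$true_mean_flow, 20 * pi * 0.25 * 60, tolerance = 1e-12)
  expect_lt(abs(fl$mean_flow - sim$true_mean_flow) / sim$true_mean_flow,
            0.05)
})

test_that("cohort truth carries the designed effects and structure", {
  des <- cohort_design(n_animals = 7)
  sim <- simulate_cohort(des, seed = 2)
  tb <- sim$truth
  expect_equal(nrow(tb), 21)
  expect_true(all(table(tb$animal_id) == 3))
  expect_true(all(tb$f + tb$v < 1))
  expect_true(all(tb$Y_DAo < tb$Y_UV))
  expect_true(all(tb$T2fb > 0 & tb$T2fb < 150))
  expect_true(all(tb$tadalafil[tb$state == "basal"] == 0))
  expect_true(all(tb$tadalafil[tb$state != "basal"] > 0))
})

test_that("zero-effect, zero-within-noise designs have equal state means", {
  wsd0 <- list(f = 0, v = 0, d = 0, d_star = 0, T2fb = 0, LVCO = 0,
               uta_frac = 0, Q_UV = 0, Y_UV = 0, Y_DAo = 0,
               Y_arterial = 0, Hb_maternal = 0, Hb_fetal = 0,
               maternal_weight = 0, MAP = 0, HR = 0)
  des <- cohort_design(null_effects = TRUE, within_sd = wsd0)
  tb <- simulate_cohort(des, seed = 6)$truth
  for (v in c("v", "f", "uta_frac", "Q_UV", "MAP"))
    expect_equal(tapply(tb[[v]], tb$state, mean),
                 tapply(tb[[v]], tb$state, mean)[c(1, 1, 1)],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generated images satisfy every consumer precondition", {
  des <- cohort_design(n_animals = 2)
  sim <- simulate_cohort(des, seed = 4, level = "images")
  expect_length(sim$images, 6)
  img <- sim$images[[1]]
  expect_s3_class(img$placentome$series, "placentome_series")
  expect_true(grid_identifiable(img$placentome$series$grid))
  expect_s3_class(img$t2prep$UV, "t2prep_series")
  expect_true(all(img$t2prep$UV$signals > 0))
  expect_s3_class(img$cine$AAo$series, "pc_cine_series")
  expect_true(max(abs(img$cine$AAo$series$phase_images)) <= pi)
})
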