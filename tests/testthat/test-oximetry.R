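test_that("central_fraction_roi keeps the promised count of interior pixels", {
  # ~100-pixel disk
  xy <- expand.grid(1:21, 1:21)
  disk <- matrix((xy[, 1] - 11)^2 + (xy[, 2] - 11)^2 <= 5.6^2, 21, 21)
  n <- sum(disk)
  roi <- central_fraction_roi(disk, 0.6)
  expect_equal(sum(roi), ceiling(0.6 * n))
  expect_true(all(disk[roi]))                  # subset of the input
  # selected pixels are the deepest: every kept pixel lies at least as far
  # from the background (brute-force Euclidean distance) as every dropped one
  bg <- which(!disk, arr.ind = TRUE)
  d_bound <- function(px) apply(px, 1, function(p)
    sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)))
  kept <- d_bound(which(roi, arr.ind = TRUE))
  dropped <- d_bound(which(disk & !roi, arr.ind = TRUE))
  expect_gte(min(kept), max(dropped))
  expect_gt(min(kept), 1)                      # all interior
})

test_that("central_fraction_roi with fraction 1 is the identity", {
  m <- matrix(c(0, 1, 1, 1, 0, 1, 0, 0, 1), 3, 3) != 0
  expect_identical(central_fraction_roi(m, 1), m)
  expect_error(central_fraction_roi(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("5x5 square ranking matches a brute-force oracle", {
  m <- matrix(TRUE, 5, 5)
  # oracle: plain-loop distance to background (border outside the image),
  # tie-broken by centroid distance then row-major order
  px <- which(m, arr.ind = TRUE)
  d_bound <- apply(px, 1, function(p)
    min(p[1], p[2], 6 - p[1], 6 - p[2]))    # exact for a full rectangle
  d_cen <- sqrt((px[, 1] - 3)^2 + (px[, 2] - 3)^2)
  ord <- order(-d_bound, d_cen, px[, 1], px[, 2])
  expected <- matrix(FALSE, 5, 5)
  expected[px[ord[1:15], , drop = FALSE]] <- TRUE
  expect_identical(central_fraction_roi(m, 0.6), expected)
  expect_equal(sum(central_fraction_roi(m, 0.6)), 15)
})

test_that("noiseless mono-exponential decay is recovered exactly", {
  tau <- c(32, 64, 96, 128, 160, 192)
  ser <- t2prep_series(tau, 100 * exp(-tau / 80))
  fit <- fit_t2_decay(ser)
  expect_true(fit$ok)
  expect_equal(fit$T2, 80, tolerance = 1e-8)
  expect_equal(fit$S0, 100, tolerance = 1e-8)
})

test_that("two-point decay has the closed-form solution", {
  fit <- fit_t2_decay(t2prep_series(c(32, 96), c(90, 30)))
  expect_equal(fit$T2, 64 / log(3), tolerance = 1e-8)
})

test_that("non-decaying series are flagged failures", {
  fit <- fit_t2_decay(t2prep_series(c(32, 64, 96), c(50, 50, 50)))
  expect_false(fit$ok)
  expect_true(is.na(fit$T2))
  rising <- fit_t2_decay(t2prep_series(c(32, 64, 96), c(30, 40, 55)))
  expect_false(rising$ok)
})

test_that("decay fit is scale-equivariant", {
  tau <- c(32, 64, 96, 128, 160, 192)
  set.seed(4)
  y <- 100 * exp(-tau / 60) * exp(stats::rnorm(6, 0, 0.02))
  f1 <- fit_t2_decay(t2prep_series(tau, y))
  f2 <- fit_t2_decay(t2prep_series(tau, 7.3 * y))
  expect_equal(f2$T2, f1$T2, tolerance = 1e-9)
  expect_equal(f2$S0, 7.3 * f1$S0, tolerance = 1e-9)
})

test_that("saturation conversion inverts the quadratic calibration", {
  cal <- oximetry_calibration(A = 5, B = 40)
  # R2 exactly A -> fully saturated
  expect_equal(as.numeric(so2_from_t2(1000 / 5, cal)), 1)
  # hand inversion: R2 = 15 s^-1 -> (15-5)/40 = 0.25 -> Y = 0.5
  expect_equal(as.numeric(so2_from_t2(1000 / 15, cal)), 0.5,
               tolerance = 1e-12)
  # round trip over the full range
  Y <- seq(0.01, 0.99, by = 0.01)
  expect_equal(as.numeric(so2_from_t2(t2_from_so2(Y, cal), cal)), Y,
               tolerance = 1e-10)
  # strictly increasing in T2 on the valid (unclamped) domain,
  # T2 > 1000/(A + B)
  T2 <- seq(25, 180, by = 5)
  expect_true(all(diff(so2_from_t2(T2, cal)) > 0))
  # T2 longer than fully-saturated blood is an error
  expect_error(so2_from_t2(1000 / 4.9, cal), "fully-oxygenated")
  # t2_to_so2 is the same conversion
  expect_equal(t2_to_so2(1000 / 15, cal), so2_from_t2(1000 / 15, cal))
})

test_that("calibration requires constants or a preset", {
  expect_error(oximetry_calibration(), "required")
  cal <- oximetry_calibration(preset = "sheep_3T")
  expect_gt(cal$A, 0); expect_gt(cal$B, 0)
  expect_error(oximetry_calibration(A = -1, B = 40), "A must")
})
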