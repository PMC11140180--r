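#' Blood T2-oxygen saturation calibration
#'
#' Quadratic (Luz-Meiboom-type) relationship between the transverse
#' relaxation rate of blood and its oxygen saturation Y:
#' \deqn{R_2 = A + B (1 - Y)^2}
#' with `R2` in s^-1. `A` is the relaxation rate of fully saturated blood
#' and `B` the desaturation coefficient; both depend on species,
#' haematocrit, field strength and the refocusing interval of the T2
#' preparation, so the constants are required configuration. A named
#' preset `"sheep_3T"` ships representative values for sheep blood at 3 T
#' (haematocrit ~0.30): `A = 4` s^-1, `B = 60` s^-1.
#'
#' @param A Relaxation rate of fully oxygenated blood (s^-1).
#' @param B Quadratic desaturation coefficient (s^-1).
#' @param species,hct Metadata tags carried along with the calibration.
#' @param preset Instead of `A`/`B`, a preset name (`"sheep_3T"`).
#' @return An `oximetry_calibration` object.
#' @export
oximetry_calibration <- function(A = NULL, B = NULL, species = "sheep",
                                 hct = NA_real_, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "sheep_3T")
    A <- 4; B <- 60; species <- "sheep"; hct <- 0.30
  }
  if (is.null(A) || is.null(B))
    stop("calibration constants A and B are required (or use a preset)",
         call. = FALSE)
  if (!is.finite(A) || A <= 0) stop("A must be positive", call. = FALSE)
  if (!is.finite(B) || B <= 0) stop("B must be positive", call. = FALSE)
  structure(list(A = A, B = B, species = species, hct = hct),
            class = "oximetry_calibration")
}

#' Convert blood T2 to oxygen saturation
#'
#' Inverts the quadratic calibration `R2 = A + B (1 - Y)^2` for the
#' saturation `Y`, taking the physical branch `Y <= 1`:
#' `Y = 1 - sqrt((1000/T2 - A) / B)` for `T2` in ms. Values are clamped to
#' `[0, 1]`; clamping at 0 is flagged via the `"clamped"` attribute. A T2
#' longer than that of fully saturated blood (i.e. `R2 < A`) beyond a small
#' tolerance is an error; within tolerance it maps to `Y = 1`.
#'
#' @param T2 Blood T2 (ms), vectorised.
#' @param calibration An [oximetry_calibration()].
#' @param tol Relative tolerance on `R2 - A` below which a slightly
#'   over-long T2 is treated as fully saturated.
#' @return SO2 fraction(s) in `[0, 1]` with a logical `"clamped"` attribute.
#' @export
so2_from_t2 <- function(T2, calibration, tol = 1e-6) {
  stopifnot(inherits(calibration, "oximetry_calibration"))
  if (any(!is.finite(T2)) || any(T2 <= 0))
    stop("T2 must be positive", call. = FALSE)
  R2 <- 1000 / T2                       # ms -> s^-1
  excess <- R2 - calibration$A
  if (any(excess < -tol * calibration$A))
    stop("T2 above fully-oxygenated calibration limit (R2 < A)",
         call. = FALSE)
  excess[excess < 0] <- 0
  Y <- 1 - sqrt(excess / calibration$B)
  clamped <- Y < 0
  Y[clamped] <- 0
  attr(Y, "clamped") <- clamped
  Y
}

#' @rdname so2_from_t2
#' @details `t2_from_so2()` is the forward map, returning T2 in ms for a
#'   saturation `Y`; `so2_from_t2(t2_from_so2(Y, cal), cal)` round-trips to
#'   machine precision.
#' @param Y SO2 fraction(s) in `[0, 1]`.
#' @export
t2_from_so2 <- function(Y, calibration) {
  stopifnot(inherits(calibration, "oximetry_calibration"))
  if (any(Y < 0 | Y > 1)) stop("Y must lie in [0, 1]", call. = FALSE)
  1000 / (calibration$A + calibration$B * (1 - Y)^2)
}

#' Central fraction of a vessel mask
#'
#' Deterministic stand-in for the manual placement of an ROI over the
#' central 60% of a vessel lumen: pixels of the input mask are ranked by
#' descending distance to the mask boundary (exact Euclidean distance to
#' the nearest background pixel, with everything outside the image counted
#' as background), ties broken by ascending distance to the mask centroid,
#' then by row-major order, and the top `ceiling(fraction * N)` pixels are
#' kept.
#'
#' @param mask 2D binary matrix (nonzero = vessel).
#' @param fraction Fraction of pixels to keep, in (0, 1]. Default 0.6.
#' @return A logical matrix of the same shape, a subset of `mask` with
#'   exactly `ceiling(fraction * sum(mask))` `TRUE` pixels.
#' @export
central_fraction_roi <- function(mask, fraction = 0.6) {
  if (length(dim(mask)) != 2L) stop("mask must be 2D", call. = FALSE)
  m <- mask != 0
  n <- sum(m)
  if (n == 0L) stop("empty mask", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  keep_n <- ceiling(fraction * n)
  if (keep_n == n) return(m)

  idx <- which(m, arr.ind = TRUE)
  # background = non-mask pixels plus a one-pixel border outside the image
  bg <- which(!m, arr.ind = TRUE)
  nr <- nrow(m); nc <- ncol(m)
  border <- rbind(cbind(0L, 0:(nc + 1L)), cbind(nr + 1L, 0:(nc + 1L)),
                  cbind(1:nr, 0L), cbind(1:nr, nc + 1L))
  bg <- rbind(bg, border)
  d_bound <- apply(idx, 1L, function(p)
    sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)))
  cen <- colMeans(idx)
  d_cen <- sqrt((idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2)
  ord <- order(-d_bound, d_cen, idx[, 1], idx[, 2])
  keep <- idx[ord[seq_len(keep_n)], , drop = FALSE]
  out <- matrix(FALSE, nr, nc)
  out[keep] <- TRUE
  out
}

#' T2-prepared vessel decay series
#'
#' @param prep_times T2 preparation times (ms), strictly increasing,
#'   at least 2. The study default is \{32, 64, 96, 128, 160, 192\} ms.
#' @param signals Mean ROI signal at each preparation time (positive).
#' @param vessel_label One of `"UV"`, `"DAo"`, `"UtV_left"`,
#'   `"UtV_right"`, `"UtA"`, `"AAo"` (or any label).
#' @return A `t2prep_series` object.
#' @export
t2prep_series <- function(prep_times, signals, vessel_label = NA_character_) {
  if (length(prep_times) < 2L || any(diff(prep_times) <= 0))
    stop("prep_times must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (length(signals) != length(prep_times))
    stop("signals and prep_times lengths differ", call. = FALSE)
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop("signals must be positive", call. = FALSE)
  structure(list(prep_times = as.numeric(prep_times),
                 signals = as.numeric(signals),
                 vessel_label = vessel_label),
            class = "t2prep_series")
}

#' Fit a mono-exponential T2 decay
#'
#' Fits `S(tau) = S0 * exp(-tau / T2)` to a T2-prepared series by
#' nonlinear least squares, initialised from the log-linear regression of
#' `log(S)` on `tau`. A non-decaying series (log-linear slope >= 0) is
#' returned as a flagged failure rather than an error.
#'
#' @param series A [t2prep_series()].
#' @return A list with `T2` (ms), `S0`, `ok` (logical), `residual_norm`
#'   and `message`.
#' @export
fit_t2_decay <- function(series) {
  stopifnot(inherits(series, "t2prep_series"))
  tau <- series$prep_times; y <- series$signals
  ll <- stats::lm.fit(cbind(1, tau), log(y))
  slope <- ll$coefficients[2]
  if (!is.finite(slope) || slope >= -1e-10)
    return(list(T2 = NA_real_, S0 = NA_real_, ok = FALSE,
                residual_norm = NA_real_,
                message = "non-decaying series: T2 not estimable"))
  start <- c(S0 = exp(ll$coefficients[[1]]), T2 = -1 / slope[[1]])
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) p[["S0"]] * exp(-tau / p[["T2"]]) - y,
    lower = c(S0 = 1e-12, T2 = 1e-6),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, maxiter = 200))
  theta <- fit$par
  list(T2 = theta[["T2"]], S0 = theta[["S0"]],
       ok = fit$info %in% 1:4 && theta[["T2"]] > 0 && theta[["T2"]] < 1e6,
       residual_norm = sqrt(fit$deviance), message = fit$message)
}

#' @rdname so2_from_t2
#' @details `t2_to_so2()` is an alias of `so2_from_t2()`; the same
#'   conversion serves both the fitted feto-placental blood T2 of the
#'   placentome model and vessel T2 oximetry.
#' @export
t2_to_so2 <- so2_from_t2
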