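#' Placentome series container
#'
#' Bundles a 4D signal volume, a 3D binary placentome mask and the
#' acquisition grid it was sampled on. The 4th dimension of `signal` must
#' match the number of grid points.
#'
#' @param signal 4D numeric array `(x, y, z, grid point)`, non-negative.
#' @param mask 3D array; nonzero marks in-mask voxels.
#' @param grid An [acquisition_grid()].
#' @return A `placentome_series` object.
#' @export
placentome_series <- function(signal, mask, grid) {
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array", call. = FALSE)
  if (dim(signal)[4] != nrow(grid))
    stop("4th dimension of signal (", dim(signal)[4],
         ") does not match grid length (", nrow(grid), ")", call. = FALSE)
  if (!identical(dim(mask), dim(signal)[1:3]))
    stop("mask dimensions must match signal volume", call. = FALSE)
  if (any(signal < 0)) stop("signal must be non-negative", call. = FALSE)
  structure(list(signal = signal, mask = array(mask != 0, dim(mask)),
                 grid = grid),
            class = "placentome_series")
}

#' Fitting control settings
#'
#' @param ftol Relative cost-reduction tolerance for the
#'   Levenberg-Marquardt solver.
#' @param maxiter Maximum number of iterations.
#' @param penalty_weight Weight of the soft penalty keeping `f + v < 1`
#'   (scaled internally by the signal amplitude).
#' @param transform `"none"` fits in natural units with box projection;
#'   `"logit"` fits unconstrained on logit/log-transformed parameters.
#' @return A list of class `decide_fit_control`.
#' @export
decide_fit_control <- function(ftol = 1e-10, maxiter = 400,
                               penalty_weight = 10,
                               transform = c("none", "logit")) {
  transform <- match.arg(transform)
  structure(list(ftol = ftol, maxiter = maxiter,
                 penalty_weight = penalty_weight, transform = transform),
            class = "decide_fit_control")
}

# parameter order used throughout the solver
.decide_par_names <- c("S0", "f", "v", "d", "d_star", "T2fb")

.decide_bounds <- function(s0_max) {
  list(lower = c(S0 = 1e-12, f = 1e-6, v = 1e-6, d = 1e-9, d_star = 1e-9,
                 T2fb = 1e-3),
       upper = c(S0 = 10 * s0_max, f = 1 - 1e-6, v = 1 - 1e-6,
                 d = 1 - 1e-9, d_star = 1 - 1e-9, T2fb = 150 - 1e-6))
}

.decide_model_vec <- function(theta, b, TE, cst) {
  theta[["S0"]] * (
    theta[["f"]] * exp(-b * theta[["d_star"]] - TE / theta[["T2fb"]]) +
    theta[["v"]] * exp(-TE / cst$T2mb) +
    (1 - theta[["f"]] - theta[["v"]]) * exp(-b * theta[["d"]] - TE / cst$T2ts))
}

# residual = model - y, with one extra soft-penalty row for f + v >= 1
.decide_residual <- function(theta, b, TE, y, cst, pen) {
  r <- .decide_model_vec(theta, b, TE, cst) - y
  c(r, pen * max(0, theta[["f"]] + theta[["v"]] - 1))
}

.decide_jacobian <- function(theta, b, TE, y, cst, pen) {
  S0 <- theta[["S0"]]; f <- theta[["f"]]; v <- theta[["v"]]
  Efb <- exp(-b * theta[["d_star"]] - TE / theta[["T2fb"]])
  Emb <- exp(-TE / cst$T2mb)
  Ets <- exp(-b * theta[["d"]] - TE / cst$T2ts)
  J <- cbind(
    S0     = f * Efb + v * Emb + (1 - f - v) * Ets,
    f      = S0 * (Efb - Ets),
    v      = S0 * (Emb - Ets),
    d      = -S0 * (1 - f - v) * b * Ets,
    d_star = -S0 * f * b * Efb,
    T2fb   = S0 * f * Efb * TE / theta[["T2fb"]]^2)
  act <- as.numeric(f + v >= 1)
  rbind(J, c(0, pen * act, pen * act, 0, 0, 0))
}

# logit/log transform pair for the unconstrained route
.to_unconstrained <- function(theta, bounds) {
  lo <- bounds$lower; hi <- bounds$upper
  z <- (theta - lo) / (hi - lo)
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  stats::qlogis(z)
}
.from_unconstrained <- function(eta, bounds) {
  bounds$lower + stats::plogis(eta) * (bounds$upper - bounds$lower)
}

.theta_to_params <- function(theta) {
  structure(as.list(theta[.decide_par_names]), class = "decide_params")
}

.fit_decide_curve <- function(y, grid, constants, init, control) {
  b <- grid$b_s_per_mm2; TE <- grid$TE_ms
  s0_max <- max(y)
  bounds <- .decide_bounds(s0_max)
  pen <- control$penalty_weight * max(s0_max, .Machine$double.eps)

  # no decay information: a flat curve cannot constrain any rate
  if (stats::sd(y) <= 1e-12 * max(abs(y), 1)) {
    return(list(params = .theta_to_params(init), residual_norm = NA_real_,
                converged = FALSE, degenerate = TRUE, iterations = 0L,
                message = "degenerate: no decay information in signal"))
  }

  ctl <- minpack.lm::nls.lm.control(ftol = control$ftol,
                                    maxiter = control$maxiter)
  solve_from <- function(start) {
    if (control$transform == "logit") {
      eta0 <- .to_unconstrained(start, bounds)
      fn <- function(eta)
        .decide_residual(.from_unconstrained(eta, bounds), b, TE, y,
                         cst = constants, pen = pen)
      fit <- minpack.lm::nls.lm(par = eta0, fn = fn, control = ctl)
      theta <- .from_unconstrained(fit$par, bounds)
    } else {
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = start, fn = .decide_residual, jac = .decide_jacobian,
        lower = bounds$lower, upper = bounds$upper,
        b = b, TE = TE, y = y, cst = constants, pen = pen, control = ctl))
      theta <- stats::setNames(as.numeric(fit$par), .decide_par_names)
    }
    list(fit = fit, theta = theta,
         rss = sum(.decide_residual(theta, b, TE, y, constants, pen)^2))
  }
  sol <- solve_from(init)
  # escape the compartment-exchange local minimum: pseudo-diffusion must be
  # faster than tissue diffusion, so a solution with d >= d_star suggests the
  # two diffusive compartments swapped roles; restart from the exchanged point
  if (sol$theta[["d"]] >= sol$theta[["d_star"]]) {
    swapped <- sol$theta
    swapped[c("d", "d_star")] <- sol$theta[c("d_star", "d")]
    swapped <- pmin(pmax(swapped, bounds$lower), bounds$upper)
    sol2 <- solve_from(swapped)
    if (sol2$rss < sol$rss) sol <- sol2
  }
  fit <- sol$fit
  theta <- sol$theta
  conv <- fit$info %in% c(1L, 2L, 3L, 4L)
  list(params = .theta_to_params(theta),
       residual_norm = sqrt(sum(.decide_residual(theta, b, TE, y,
                                                 constants, 0)^2)),
       converged = conv, degenerate = FALSE,
       iterations = fit$niter, message = fit$message)
}

.init_theta <- function(init, s0) {
  if (is.null(init)) {
    init <- decide_params()
    init$S0 <- NA_real_   # default start: maximum observed signal
  }
  c(S0 = if (is.null(init$S0) || is.na(init$S0)) s0 else init$S0,
    f = init$f, v = init$v, d = init$d, d_star = init$d_star,
    T2fb = init$T2fb)
}

#' Fit the placentome model to the ROI-average signal curve
#'
#' Averages the in-mask signal at each grid point and fits the six-parameter
#' three-compartment model by box-constrained nonlinear least squares
#' (Levenberg-Marquardt). Used both as an ROI-level estimate and as the
#' initialisation stage of the voxelwise fit.
#'
#' @param series A [placentome_series()].
#' @param constants Fixed compartment constants, [decide_constants()].
#' @param init Optional initial [decide_params()]; by default the mid-box
#'   start `f = v = 0.2`, `d = 1.5e-3`, `d_star = 0.03`, `T2fb = 75`, with
#'   `S0` initialised at the maximum observed signal.
#' @param control A [decide_fit_control()].
#' @return A list with elements `params` ([decide_params()]),
#'   `residual_norm`, `converged`, `degenerate`, `iterations`, `message`.
#' @export
fit_decide_roi <- function(series, constants = decide_constants(),
                           init = NULL, control = decide_fit_control()) {
  if (!inherits(series, "placentome_series"))
    stop("series must be a placentome_series", call. = FALSE)
  if (!any(series$mask)) stop("empty mask", call. = FALSE)
  if (!grid_identifiable(series$grid))
    stop("acquisition grid is non-identifiable: need >= 6 distinct points ",
         "spanning >= 2 b-values and >= 2 echo times", call. = FALSE)
  nvol <- dim(series$signal)[4]
  sig <- matrix(series$signal, ncol = nvol)
  y <- colMeans(sig[as.vector(series$mask), , drop = FALSE])
  theta0 <- .init_theta(init, max(y))
  .fit_decide_curve(y, series$grid, constants, theta0, control)
}

#' Voxelwise placentome model fit
#'
#' Two-stage constrained fit: stage 1 fits the ROI-average curve
#' ([fit_decide_roi()]); stage 2 fits every in-mask voxel independently,
#' initialised at the stage-1 estimate (with `S0` re-initialised at the
#' voxel's maximum signal). Voxels whose optimiser fails are flagged, never
#' fatal; out-of-mask voxels carry `NA`.
#'
#' @inheritParams fit_decide_roi
#' @return A `decide_maps` object: one 3D array per model parameter,
#'   plus `residual_norm`, `iterations`, `converged` and `fitted`
#'   diagnostic volumes, and the stage-1 `roi_fit`.
#' @export
fit_decide_voxelwise <- function(series, constants = decide_constants(),
                                 control = decide_fit_control()) {
  roi <- fit_decide_roi(series, constants, control = control)
  dims <- dim(series$signal)[1:3]
  nvol <- dim(series$signal)[4]
  sig <- matrix(series$signal, ncol = nvol)
  idx <- which(as.vector(series$mask))

  maps <- lapply(.decide_par_names, function(nm) array(NA_real_, dims))
  names(maps) <- .decide_par_names
  resn <- array(NA_real_, dims)
  iters <- array(NA_integer_, dims)
  conv <- array(NA, dims)

  for (i in idx) {
    y <- sig[i, ]
    theta0 <- .init_theta(roi$params, max(y))
    theta0["S0"] <- max(y)
    fit <- .fit_decide_curve(y, series$grid, constants, theta0, control)
    # guard against local minima: retry from the default mid-box start
    # and keep the better of the two solutions
    if (!fit$degenerate) {
      alt <- .fit_decide_curve(y, series$grid, constants,
                               .init_theta(NULL, max(y)), control)
      if (!alt$degenerate && isTRUE(alt$residual_norm < fit$residual_norm))
        fit <- alt
    }
    for (nm in .decide_par_names) maps[[nm]][i] <- fit$params[[nm]]
    resn[i] <- fit$residual_norm
    iters[i] <- fit$iterations
    conv[i] <- fit$converged && !fit$degenerate
  }
  structure(c(maps, list(residual_norm = resn, iterations = iters,
                         converged = conv, fitted = series$mask,
                         roi_fit = roi)),
            class = "decide_maps")
}
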