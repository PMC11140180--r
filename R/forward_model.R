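#' Three-compartment placentome model parameters
#'
#' Construct and validate the free parameters of the DECIDE
#' (diffusion-relaxation combined) placentome signal model: the
#' feto-placental blood volume fraction `f`, trophoblast/tissue apparent
#' diffusivity `d`, feto-placental blood pseudo-diffusivity `d_star`,
#' feto-placental blood transverse relaxation time `T2fb`, the maternal
#' blood volume fraction `v`, and the unattenuated signal amplitude `S0`.
#'
#' Box constraints follow the fitting constraints used to stabilise the
#' voxelwise fit: `0 < f < 1`, `0 < v < 1`, `0 < d < 1` mm^2/s,
#' `0 < d_star < 1` mm^2/s, `0 < T2fb < 150` ms. Additionally the tissue
#' fraction `1 - f - v` must be positive for the model to be physical.
#'
#' @param f Feto-placental blood volume fraction (dimensionless).
#' @param d Tissue apparent diffusivity (mm^2/s).
#' @param d_star Pseudo-diffusivity of feto-placental blood (mm^2/s).
#' @param T2fb Feto-placental blood T2 (ms); the model uses
#'   `R2fb = 1/T2fb`.
#' @param v Maternal blood volume fraction (dimensionless).
#' @param S0 Signal amplitude at `b = 0`, `TE = 0` (arbitrary units).
#' @return An object of class `decide_params` (named list).
#' @seealso [decide_signal()], [fit_decide_roi()]
#' @export
decide_params <- function(f = 0.2, d = 1.5e-3, d_star = 0.03,
                          T2fb = 75, v = 0.2, S0 = 1) {
  p <- list(f = f, d = d, d_star = d_star, T2fb = T2fb, v = v, S0 = S0)
  validate_decide_params(p)
  structure(p, class = "decide_params")
}

#' @rdname decide_params
#' @param p A list with the six parameter fields.
#' @export
validate_decide_params <- function(p) {
  chk <- function(ok, name, what) {
    if (!all(is.finite(p[[name]])) || !all(ok))
      stop("invalid parameter '", name, "': ", what, call. = FALSE)
  }
  chk(p$f > 0 & p$f < 1, "f", "must lie in (0, 1)")
  chk(p$v > 0 & p$v < 1, "v", "must lie in (0, 1)")
  chk(p$f + p$v < 1, "v", "f + v must be < 1 (tissue fraction non-negative)")
  chk(p$d > 0 & p$d < 1, "d", "must lie in (0, 1) mm^2/s")
  chk(p$d_star > 0 & p$d_star < 1, "d_star", "must lie in (0, 1) mm^2/s")
  chk(p$T2fb > 0 & p$T2fb < 150, "T2fb", "must lie in (0, 150) ms")
  chk(p$S0 > 0, "S0", "must be positive")
  invisible(p)
}

#' Fixed relaxation constants of the non-fitted compartments
#'
#' Literature-based transverse relaxation times at 3 T for highly saturated
#' maternal blood and for placental tissue. Both are held fixed during
#' model fitting and are configurable.
#'
#' @param T2mb Maternal blood T2 (ms). Default 150.
#' @param T2ts Tissue T2 (ms). Default 42.
#' @return An object of class `decide_constants`.
#' @export
decide_constants <- function(T2mb = 150, T2ts = 42) {
  if (!is.finite(T2mb) || T2mb <= 0) stop("T2mb must be positive", call. = FALSE)
  if (!is.finite(T2ts) || T2ts <= 0) stop("T2ts must be positive", call. = FALSE)
  structure(list(T2mb = T2mb, T2ts = T2ts), class = "decide_constants")
}

#' Diffusion/relaxation acquisition grid
#'
#' The ordered list of (b-value, echo time) sample points a placentome
#' series is measured on. A six-parameter fit needs at least 6 distinct
#' points spanning at least 2 distinct b-values and 2 distinct echo times;
#' grids failing this are rejected as non-identifiable.
#'
#' @param b Diffusion weightings (s/mm^2), one per acquired volume.
#' @param TE Echo times (ms), one per acquired volume (recycled against
#'   `b` if scalar).
#' @return A data.frame of class `acquisition_grid` with columns
#'   `b_s_per_mm2` and `TE_ms`.
#' @export
acquisition_grid <- function(b, TE) {
  g <- data.frame(b_s_per_mm2 = as.numeric(b), TE_ms = as.numeric(TE))
  if (any(!is.finite(g$b_s_per_mm2)) || any(g$b_s_per_mm2 < 0))
    stop("b-values must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(g$TE_ms)) || any(g$TE_ms <= 0))
    stop("echo times must be finite and > 0", call. = FALSE)
  class(g) <- c("acquisition_grid", "data.frame")
  g
}

#' @rdname acquisition_grid
#' @details `default_grid()` returns the package default: the full cross
#'   of b in \{0, 50, 100, 200, 400, 600\} s/mm^2 with TE in
#'   \{72, 96, 120, 144, 192\} ms (30 points).
#' @export
default_grid <- function() {
  g <- expand.grid(b_s_per_mm2 = c(0, 50, 100, 200, 400, 600),
                   TE_ms = c(72, 96, 120, 144, 192))
  acquisition_grid(g$b_s_per_mm2, g$TE_ms)
}

#' @rdname acquisition_grid
#' @param grid An `acquisition_grid`.
#' @return `grid_identifiable()`: logical, `TRUE` when the grid supports
#'   the six-parameter fit.
#' @export
grid_identifiable <- function(grid) {
  nrow(unique(grid)) >= 6 &&
    length(unique(grid$b_s_per_mm2)) >= 2 &&
    length(unique(grid$TE_ms)) >= 2
}

#' Forward three-compartment placentome signal
#'
#' Evaluates the DECIDE signal model
#' \deqn{S(b, TE) = S_0 [\, f e^{-b d^*} e^{-TE/T_{2fb}} +
#'   v e^{-TE/T_{2mb}} + (1 - f - v) e^{-b d} e^{-TE/T_{2ts}} \,]}
#' where the feto-placental blood compartment (fraction `f`) carries the
#' pseudo-diffusivity `d_star` and blood relaxation `T2fb`, the maternal
#' blood compartment (fraction `v`) carries no diffusion attenuation, and
#' the tissue compartment carries diffusivity `d` and tissue relaxation.
#'
#' At `b = 0`, `TE = 0` the compartment fractions sum to 1 and the model
#' returns exactly `S0`.
#'
#' @param params A [decide_params()] object (or list with its fields).
#' @param constants A [decide_constants()] object.
#' @param b Diffusion weighting(s), s/mm^2 (vectorised).
#' @param TE Echo time(s), ms (vectorised, recycled against `b`).
#' @param validate Check parameter invariants (default `TRUE`).
#' @return Signal in the units of `S0`; strictly positive and `<= S0`.
#' @examples
#' p <- decide_params(f = 0.3, v = 0.2, d = 1.5e-3, d_star = 0.03,
#'                    T2fb = 60, S0 = 1)
#' decide_signal(p, decide_constants(), b = 200, TE = 96)
#' @export
decide_signal <- function(params, constants = decide_constants(), b, TE,
                          validate = TRUE) {
  if (validate) validate_decide_params(params)
  if (any(b < 0)) stop("b must be >= 0", call. = FALSE)
  if (any(TE < 0)) stop("TE must be >= 0", call. = FALSE)
  # written via expm1 so the compartment fractions sum to 1 exactly and
  # the signal at b = 0, TE = 0 is bitwise equal to S0
  with(c(params, constants),
    S0 * (1 + f * expm1(-b * d_star - TE / T2fb) +
          v * expm1(-TE / T2mb) +
          (1 - f - v) * expm1(-b * d - TE / T2ts)))
}
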