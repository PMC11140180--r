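#' Phase-contrast cine series
#'
#' Per-cardiac-phase phase and magnitude images for one vessel, with the
#' velocity-encoding limit and pixel geometry needed to turn phase into
#' flow. Phase values must lie within `[-pi, pi]`; aliased (wrapped) input
#' is rejected, not unwrapped.
#'
#' @param phase_images 3D array `(x, y, cardiac phase)` of phase in
#'   radians.
#' @param magnitude_images Matching 3D array (optional, may be `NULL`).
#' @param venc Velocity-encoding limit (cm/s), > 0.
#' @param pixel_area Pixel area (cm^2), > 0.
#' @param rr_interval R-R interval (ms), metadata only.
#' @param vessel_label Vessel tag, e.g. `"AAo"`, `"UtA_left"`,
#'   `"UtA_right"`, `"UV"`.
#' @return A `pc_cine_series` object.
#' @export
pc_cine_series <- function(phase_images, magnitude_images = NULL, venc,
                           pixel_area, rr_interval = NA_real_,
                           vessel_label = NA_character_) {
  if (length(dim(phase_images)) == 2L)
    phase_images <- array(phase_images, c(dim(phase_images), 1L))
  if (length(dim(phase_images)) != 3L)
    stop("phase_images must be (x, y, phase)", call. = FALSE)
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0", call. = FALSE)
  if (!is.finite(pixel_area) || pixel_area <= 0)
    stop("pixel_area must be > 0", call. = FALSE)
  if (any(abs(phase_images) > pi + 1e-9))
    stop("phase values outside [-pi, pi]: aliased input must be unwrapped ",
         "upstream", call. = FALSE)
  if (!is.null(magnitude_images) &&
      !identical(dim(magnitude_images), dim(phase_images)))
    stop("magnitude and phase stacks must be congruent", call. = FALSE)
  structure(list(phase_images = phase_images,
                 magnitude_images = magnitude_images,
                 venc = venc, pixel_area = pixel_area,
                 n_phases = dim(phase_images)[3],
                 rr_interval = rr_interval, vessel_label = vessel_label),
            class = "pc_cine_series")
}

#' Convert phase to velocity
#'
#' Standard phase-contrast reconstruction: `v = venc * phase / pi`, so a
#' phase of `+/-pi` maps to `+/-VENC`. Sign is preserved.
#'
#' @param phase Phase in radians, `|phase| <= pi` (vectorised).
#' @param venc Velocity-encoding limit (cm/s).
#' @return Velocity in cm/s.
#' @export
phase_to_velocity <- function(phase, venc) {
  if (any(abs(phase) > pi + 1e-9))
    stop("|phase| > pi: aliased/wrapped input not supported", call. = FALSE)
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0", call. = FALSE)
  venc * phase / pi
}

#' Vessel flow from a phase-contrast cine series
#'
#' Per-cardiac-phase flow is the sum over the ROI of velocity times pixel
#' area (cm^3/s), converted to mL/min; the reported mean flow is the
#' unweighted mean over cardiac phases (uniform phase sampling).
#'
#' @param series A [pc_cine_series()].
#' @param roi 2D binary mask on the image grid.
#' @return A `flow_result` list: `mean_flow` (mL/min), `per_phase_flow`,
#'   `vessel_label`.
#' @export
roi_flow <- function(series, roi) {
  stopifnot(inherits(series, "pc_cine_series"))
  if (!identical(dim(roi), dim(series$phase_images)[1:2]))
    stop("ROI dimensions must match the image grid", call. = FALSE)
  m <- roi != 0
  if (!any(m)) stop("empty ROI", call. = FALSE)
  per_phase <- vapply(seq_len(series$n_phases), function(k) {
    v <- phase_to_velocity(series$phase_images[, , k][m], series$venc)
    sum(v) * series$pixel_area * 60   # cm/s * cm^2 -> cm^3/s -> mL/min
  }, numeric(1))
  structure(list(mean_flow = mean(per_phase), per_phase_flow = per_phase,
                 vessel_label = series$vessel_label),
            class = "flow_result")
}

#' Total uterine artery flow
#'
#' Uterine artery flow is the sum of the left and right uterine artery
#' mean flows.
#'
#' @param left,right `flow_result` objects (or lists with `mean_flow`)
#'   labelled as left/right uterine artery.
#' @return Total mean flow in mL/min.
#' @export
total_uta_flow <- function(left, right) {
  lab <- function(x) if (is.null(x$vessel_label)) NA_character_ else x$vessel_label
  ok <- function(l, want) is.na(l) || grepl(want, l, ignore.case = TRUE)
  if (!ok(lab(left), "uta|uterine") || !ok(lab(right), "uta|uterine"))
    stop("vessel-label mismatch: expected uterine artery flow results",
         call. = FALSE)
  left$mean_flow + right$mean_flow
}

#' Normalise a flow measurement
#'
#' Either indexes a flow to maternal weight (mL/min/kg) or expresses it as
#' a percentage of left ventricular cardiac output.
#'
#' @param flow Flow in mL/min.
#' @param weight Maternal weight (kg); used when `to = "weight"`.
#' @param lvco LVCO (mL/min); used when `to = "lvco"`.
#' @param to `"weight"` or `"lvco"`.
#' @return mL/min/kg, or % of LVCO.
#' @export
normalize_flow <- function(flow, weight = NULL, lvco = NULL,
                           to = c("weight", "lvco")) {
  to <- match.arg(to)
  den <- if (to == "weight") weight else lvco
  if (is.null(den) || any(!is.finite(den)) || any(den <= 0))
    stop("denominator (", to, ") must be positive", call. = FALSE)
  if (to == "weight") flow / den else 100 * flow / den
}
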