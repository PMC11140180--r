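#' Read and write NIfTI-1 images
#'
#' Thin wrappers over RNifti preserving shape, affine and values
#' (bit-exactly for integer types, to float32 precision otherwise).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_image()`: an `niftiImage` array with affine/header
#'   attributes attached.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path, call. = FALSE)
  RNifti::readNifti(path)
}

#' @rdname read_image
#' @param data Numeric array to write.
#' @param template Optional image supplying the affine/header.
#' @export
write_image <- function(data, path, template = NULL) {
  if (is.null(template)) RNifti::writeNifti(data, path)
  else RNifti::writeNifti(RNifti::asNifti(data, reference = template), path)
  invisible(path)
}

#' Read an acquisition grid sidecar table
#'
#' CSV with columns `b_s_per_mm2`, `TE_ms` and optionally `volume_index`
#' (0-based order of the volumes in the 4D series).
#'
#' @param path CSV path.
#' @return An [acquisition_grid()].
#' @export
read_acquisition_grid <- function(path) {
  g <- utils::read.csv(path)
  need <- c("b_s_per_mm2", "TE_ms")
  if (!all(need %in% names(g)))
    stop("grid table must have columns b_s_per_mm2, TE_ms", call. = FALSE)
  if ("volume_index" %in% names(g)) g <- g[order(g$volume_index), ]
  acquisition_grid(g$b_s_per_mm2, g$TE_ms)
}

#' Load a placentome series from NIfTI volumes and a grid table
#'
#' @param signal_path 4D NIfTI of the diffusion-relaxation series.
#' @param mask_path 3D NIfTI placentome mask (nonzero = in mask).
#' @param grid_path CSV sidecar (see [read_acquisition_grid()]).
#' @return A [placentome_series()].
#' @export
load_placentome_series <- function(signal_path, mask_path, grid_path) {
  sig <- read_image(signal_path)
  mask <- read_image(mask_path)
  grid <- read_acquisition_grid(grid_path)
  placentome_series(array(as.numeric(sig), dim(sig)),
                    array(as.numeric(mask) != 0, dim(mask)), grid)
}

# schema of recognised configuration keys and their defaults
.config_schema <- function() list(
  seed = 1L,
  n_animals = 7L,
  v_increase_TAD2 = 0.08,
  uta_fraction_decrease = 0.04,
  map_decrease = 10,
  null_effects = FALSE,
  image_snr = 50,
  t2prep_snr = 100,
  calibration = list(preset = "sheep_3T"),
  constants = list(T2mb = 150, T2ts = 42),
  fit = list(ftol = 1e-10, maxiter = 400, transform = "none"),
  variables = c("f", "v", "d", "d_star", "T2fb", "SO2_fp",
                "LVCO", "Q_UtA", "Q_UtA_pct_LVCO", "Q_UtA_per_kg",
                "Q_UV", "fetal_DO2", "fetal_VO2", "OEF",
                "UtA_DO2_pct_available"),
  out = NULL)

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_cohort_pipeline()] from a
#' YAML file and/or explicit overrides. Unknown keys are rejected; every
#' key has a documented default (see the schema printed by
#' `str(pipeline_config())`).
#'
#' @param path Optional YAML file.
#' @param ... Named overrides of schema keys (applied after the file).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- .config_schema()
  user <- list()
  if (!is.null(path)) user <- yaml::read_yaml(path)
  user <- utils::modifyList(user, list(...))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, user)
  # a user-supplied calibration replaces the default outright (no merging
  # of the preset with partial constants)
  if ("calibration" %in% names(user)) cfg$calibration <- user$calibration
  if (is.null(cfg$calibration$A) && is.null(cfg$calibration$preset))
    stop("missing calibration: supply constants A and B or a preset",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# stable fingerprint of a config for provenance headers
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write a results object as JSON with a provenance header
#'
#' @param x List or data.frame of results.
#' @param path Output path.
#' @param config The `pipeline_config` in force.
#' @param seed Seed used.
#' @return The path, invisibly.
#' @export
write_results_json <- function(x, path, config = NULL, seed = NULL) {
  out <- list(provenance = list(
    package = "decidemri",
    version = as.character(utils::packageVersion("decidemri")),
    config_hash = if (is.null(config)) NA else .config_hash(config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    results = x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
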