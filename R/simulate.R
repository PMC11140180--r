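#' Noise specification for simulated magnitude images
#'
#' @param model `"rician"` (magnitude of a complex Gaussian perturbation,
#'   the default for magnitude MRI), `"gaussian"`, or `"none"`.
#' @param snr Signal-to-noise ratio: reference signal divided by the
#'   complex noise standard deviation. Must be > 0 (ignored for
#'   `"none"`).
#' @param seed Optional RNG seed applied by the consuming simulator.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(model = c("rician", "gaussian", "none"), snr = Inf,
                       seed = NULL) {
  model <- match.arg(model)
  if (model != "none" && (!is.finite(snr) || snr <= 0) && !is.infinite(snr))
    stop("snr must be > 0", call. = FALSE)
  structure(list(model = model, snr = snr, seed = seed),
            class = "noise_spec")
}

# apply magnitude noise with standard deviation sigma
.apply_noise <- function(signal, sigma, model) {
  if (model == "none" || sigma <= 0) return(signal)
  n <- length(signal)
  if (model == "rician") {
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  } else {
    signal + stats::rnorm(n, 0, sigma)
  }
}

#' Simulate a placentome diffusion-relaxation series
#'
#' Generates the noiseless three-compartment signal voxel by voxel from a
#' block-structured ground truth, then applies magnitude noise. The noise
#' standard deviation is set so that the requested SNR holds on the least
#' attenuated volume (minimum b, then minimum TE): `sigma = mean signal of
#' that volume / snr`.
#'
#' @param params_list List of [decide_params()], one per block.
#' @param block_labels 3D integer array assigning each voxel a block
#'   (index into `params_list`); 0 marks background (out of mask).
#' @param grid An [acquisition_grid()]; warns (but proceeds) if
#'   non-identifiable.
#' @param noise A [noise_spec()].
#' @param constants [decide_constants()].
#' @return A list: `series` ([placentome_series()]), `truth` (one 3D map
#'   per parameter, `NA` outside the mask), `sigma` (noise SD used).
#' @export
simulate_placentome <- function(params_list, block_labels,
                                grid = default_grid(),
                                noise = noise_spec("none"),
                                constants = decide_constants()) {
  if (!grid_identifiable(grid))
    warning("acquisition grid is non-identifiable; generated data cannot ",
            "support a six-parameter fit", call. = FALSE)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  lab <- as.integer(block_labels)
  dims <- dim(block_labels)
  nvol <- nrow(grid)
  sig <- matrix(0, length(lab), nvol)
  truth <- lapply(.decide_par_names,
                  function(nm) array(NA_real_, dims))
  names(truth) <- .decide_par_names
  for (blk in seq_along(params_list)) {
    vox <- which(lab == blk)
    if (!length(vox)) next
    p <- params_list[[blk]]
    validate_decide_params(p)
    s <- decide_signal(p, constants, grid$b_s_per_mm2, grid$TE_ms,
                       validate = FALSE)
    sig[vox, ] <- matrix(s, length(vox), nvol, byrow = TRUE)
    for (nm in .decide_par_names) truth[[nm]][vox] <- p[[nm]]
  }
  mask <- array(lab > 0, dims)
  # reference volume: minimum b, then minimum TE
  ref <- order(grid$b_s_per_mm2, grid$TE_ms)[1]
  sigma <- if (noise$model == "none" || is.infinite(noise$snr)) 0 else
    mean(sig[lab > 0, ref]) / noise$snr
  noisy <- array(.apply_noise(as.vector(sig), sigma, noise$model),
                 c(dims, nvol))
  list(series = placentome_series(noisy, mask, grid), truth = truth,
       sigma = sigma)
}

#' Simulate a T2-prepared vessel decay series
#'
#' Mono-exponential decay `S0 exp(-tau/T2)` at the given preparation
#' times, with magnitude noise at `sigma = S0 / snr`.
#'
#' @param T2 True T2 (ms).
#' @param S0 Signal amplitude.
#' @param prep_times Preparation times (ms); study default
#'   \{32, 64, 96, 128, 160, 192\}.
#' @param noise A [noise_spec()].
#' @param vessel_label Label carried on the series.
#' @return A [t2prep_series()].
#' @export
simulate_t2prep <- function(T2, S0 = 100,
                            prep_times = c(32, 64, 96, 128, 160, 192),
                            noise = noise_spec("none"),
                            vessel_label = NA_character_) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  s <- S0 * exp(-prep_times / T2)
  sigma <- if (noise$model == "none" || is.infinite(noise$snr)) 0 else
    S0 / noise$snr
  s <- .apply_noise(s, sigma, noise$model)
  t2prep_series(prep_times, pmax(s, .Machine$double.eps),
                vessel_label = vessel_label)
}

#' Simulate a phase-contrast cine acquisition of a circular vessel
#'
#' Places a vessel of radius `radius_mm` at the image centre with either a
#' plug or parabolic velocity profile (peak `vmax`), encodes velocity into
#' phase as `phi = pi v / venc`, and modulates velocity over the cardiac
#' cycle by `1 + waveform_amp * sin(2 pi k / n_phases)` (mean 1 over a full
#' cycle when `n_phases` divides evenly). The analytic mean flow is
#' returned alongside: `vmax * pi R^2` (plug) or `vmax/2 * pi R^2`
#' (parabolic), times the waveform mean.
#'
#' @param profile `"plug"` or `"parabolic"`.
#' @param vmax Peak velocity (cm/s); must be below `venc` unless
#'   `allow_aliasing = TRUE`.
#' @param radius_mm Vessel radius (mm).
#' @param venc Velocity-encoding limit (cm/s).
#' @param pixel_mm In-plane pixel size (mm, isotropic).
#' @param n_phases Cardiac phases (study acquisitions use ~15).
#' @param waveform_amp Amplitude of the sinusoidal velocity modulation.
#' @param noise A [noise_spec()]; complex noise at `1/snr` of unit
#'   magnitude perturbs magnitude and phase jointly.
#' @param margin_mm Background margin around the vessel.
#' @param allow_aliasing Permit `vmax >= venc`, producing wrapped raw
#'   phase (for testing the aliasing rejection downstream).
#' @return A list: `series` (a [pc_cine_series()], or `NULL` when the raw
#'   phase is aliased), `phase_images` (raw), `roi` (true vessel mask),
#'   `true_mean_flow` (mL/min), `pixel_area` (cm^2).
#' @export
simulate_pc_cine <- function(profile = c("parabolic", "plug"), vmax,
                             radius_mm, venc, pixel_mm = 0.5, n_phases = 8,
                             waveform_amp = 0, noise = noise_spec("none"),
                             margin_mm = 2, allow_aliasing = FALSE) {
  profile <- match.arg(profile)
  if (!allow_aliasing && vmax >= venc)
    stop("vmax must be below venc (or set allow_aliasing = TRUE)",
         call. = FALSE)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  half <- radius_mm + margin_mm
  n <- ceiling(2 * half / pixel_mm)
  coord <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  r2 <- outer(coord^2, coord^2, `+`)
  inside <- r2 <= radius_mm^2
  vel <- matrix(0, n, n)
  vel[inside] <- if (profile == "plug") vmax else
    vmax * (1 - r2[inside] / radius_mm^2)

  w <- 1 + waveform_amp * sin(2 * pi * (seq_len(n_phases) - 1) / n_phases)
  phase <- array(0, c(n, n, n_phases))
  for (k in seq_len(n_phases)) phase[, , k] <- pi * vel * w[k] / venc
  mag <- array(1, dim(phase))
  if (noise$model != "none" && is.finite(noise$snr)) {
    sigma <- 1 / noise$snr
    z <- mag * exp(1i * phase) +
      complex(real = stats::rnorm(length(phase), 0, sigma),
              imaginary = stats::rnorm(length(phase), 0, sigma))
    phase <- array(Arg(z), dim(phase))
    mag <- array(Mod(z), dim(mag))
  }
  area_cm2 <- pi * (radius_mm / 10)^2
  base_flow <- if (profile == "plug") vmax * area_cm2 else
    vmax / 2 * area_cm2
  true_flow <- base_flow * mean(w) * 60    # cm^3/s -> mL/min
  pixel_area <- (pixel_mm / 10)^2
  series <- if (max(abs(phase)) <= pi + 1e-12)
    pc_cine_series(phase, mag, venc = venc, pixel_area = pixel_area)
  else NULL
  list(series = series, phase_images = phase, roi = inside,
       true_mean_flow = true_flow, pixel_area = pixel_area)
}

#' Cohort study design for the synthetic generator
#'
#' Defines the ground-truth distributions and injected state effects of a
#' simulated cohort: `n_animals` ewes each measured in three states
#' (basal, then two post-treatment windows TAD1/TAD2). Between-animal
#' variability is modelled as lognormal multipliers on flows and additive
#' normal shifts on fractions/saturations (clamped to valid ranges);
#' within-animal state-to-state fluctuation is additive normal. The
#' default effects mirror the study conditions: maternal placentome blood
#' volume fraction `v` raised at TAD2, the uterine fraction of cardiac
#' output lowered at both TAD windows, maternal arterial pressure lowered
#' at both TAD windows, and no true effect on any fetal oxygen endpoint or
#' on `f`, `d`, `d_star`, `T2fb` or umbilical flow.
#'
#' @param n_animals Number of animals (default 7).
#' @param v_increase_TAD2 Additive shift of `v` at TAD2 (default +0.08).
#' @param uta_fraction_decrease Absolute decrease of UtA flow as a
#'   fraction of LVCO at TAD1 and TAD2 (default 0.04, i.e. 4 points of
#'   percentage).
#' @param map_decrease Maternal MAP decrease (mmHg) at TAD1/TAD2.
#' @param null_effects Set `TRUE` to switch every injected effect off
#'   (null design for type-I error studies).
#' @param means,between_sd,within_sd Named lists overriding any default
#'   ground-truth mean / between-animal SD / within-animal SD.
#' @param image_snr SNR of simulated placentome volumes.
#' @param t2prep_snr SNR of simulated T2-prep series.
#' @param placentome_dim Dimensions of each simulated placentome volume.
#' @param n_phases Cardiac phases per cine simulation.
#' @param calibration [oximetry_calibration()] used to map saturations to
#'   vessel T2 and back.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_animals = 7, v_increase_TAD2 = 0.08,
                          uta_fraction_decrease = 0.04, map_decrease = 10,
                          null_effects = FALSE, means = list(),
                          between_sd = list(), within_sd = list(),
                          image_snr = 50, t2prep_snr = 100,
                          placentome_dim = c(6, 6, 1), n_phases = 8,
                          calibration = oximetry_calibration(preset = "sheep_3T")) {
  if (n_animals < 2) stop("n_animals must be >= 2", call. = FALSE)
  mu <- utils::modifyList(list(
    f = 0.25, v = 0.30, d = 1.5e-3, d_star = 0.03, T2fb = 90,
    LVCO = 8000, uta_frac = 0.16, Q_UV = 700,
    Y_UV = 0.80, Y_DAo = 0.55, Y_arterial = 0.95,
    Hb_maternal = 80, Hb_fetal = 95, maternal_weight = 60,
    MAP = 90, HR = 100,
    tadalafil_TAD1 = 1270, tadalafil_TAD2 = 318), means)
  bsd <- utils::modifyList(list(
    f = 0.04, v = 0.05, d = 2e-4, d_star = 5e-3, T2fb = 8,
    LVCO = 0.12, uta_frac = 0.03, Q_UV = 0.15,
    Y_UV = 0.04, Y_DAo = 0.05, Y_arterial = 0.015,
    Hb_maternal = 8, Hb_fetal = 6, maternal_weight = 6,
    MAP = 8, HR = 10,
    tadalafil_TAD1 = 740, tadalafil_TAD2 = 108), between_sd)
  wsd <- utils::modifyList(list(
    f = 0.015, v = 0.02, d = 1e-4, d_star = 2e-3, T2fb = 3,
    LVCO = 0.05, uta_frac = 0.012, Q_UV = 0.06,
    Y_UV = 0.02, Y_DAo = 0.025, Y_arterial = 0.008,
    Hb_maternal = 2, Hb_fetal = 2, maternal_weight = 0,
    MAP = 4, HR = 4), within_sd)
  eff <- if (null_effects) list(v_TAD2 = 0, uta_frac = 0, MAP = 0) else
    list(v_TAD2 = v_increase_TAD2, uta_frac = -uta_fraction_decrease,
         MAP = -map_decrease)
  structure(list(n_animals = n_animals,
                 states = c("basal", "TAD1", "TAD2"),
                 means = mu, between_sd = bsd, within_sd = wsd,
                 effects = eff, image_snr = image_snr,
                 t2prep_snr = t2prep_snr, placentome_dim = placentome_dim,
                 n_phases = n_phases, calibration = calibration),
            class = "cohort_design")
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ground-truth table: one row per animal x state
.simulate_truth <- function(design) {
  mu <- design$means; bsd <- design$between_sd; wsd <- design$within_sd
  n <- design$n_animals; states <- design$states
  add_var <- function(base, b, w) {
    ai <- stats::rnorm(n, 0, b)
    base + rep(ai, each = length(states)) +
      stats::rnorm(n * length(states), 0, w)
  }
  mult_var <- function(base, bcv, wcv) {
    ai <- exp(stats::rnorm(n, 0, bcv))
    base * rep(ai, each = length(states)) *
      exp(stats::rnorm(n * length(states), 0, wcv))
  }
  k <- length(states)
  tb <- data.frame(
    animal_id = rep(sprintf("ewe%02d", seq_len(n)), each = k),
    state = factor(rep(states, n), levels = states),
    stringsAsFactors = FALSE)
  is_tad <- tb$state %in% c("TAD1", "TAD2")
  tb$f <- .clamp(add_var(mu$f, bsd$f, wsd$f), 0.02, 0.9)
  tb$v <- .clamp(add_var(mu$v, bsd$v, wsd$v) +
                   design$effects$v_TAD2 * (tb$state == "TAD2"), 0.02, 0.9)
  over <- tb$f + tb$v > 0.95            # keep tissue fraction physical
  tb$f[over] <- tb$f[over] * 0.95 / (tb$f[over] + tb$v[over])
  tb$v[over] <- tb$v[over] * 0.95 / (tb$f[over] + tb$v[over])
  tb$d <- .clamp(add_var(mu$d, bsd$d, wsd$d), 1e-5, 0.99)
  tb$d_star <- .clamp(add_var(mu$d_star, bsd$d_star, wsd$d_star), 1e-4, 0.99)
  tb$T2fb <- .clamp(add_var(mu$T2fb, bsd$T2fb, wsd$T2fb), 5, 145)
  tb$LVCO <- mult_var(mu$LVCO, bsd$LVCO, wsd$LVCO)
  tb$uta_frac <- .clamp(add_var(mu$uta_frac, bsd$uta_frac, wsd$uta_frac) +
                          design$effects$uta_frac * is_tad, 0.02, 0.6)
  tb$Q_UtA <- tb$uta_frac * tb$LVCO
  tb$Q_UV <- mult_var(mu$Q_UV, bsd$Q_UV, wsd$Q_UV)
  tb$Y_UV <- .clamp(add_var(mu$Y_UV, bsd$Y_UV, wsd$Y_UV), 0.05, 0.97)
  tb$Y_DAo <- .clamp(add_var(mu$Y_DAo, bsd$Y_DAo, wsd$Y_DAo), 0.05, 0.97)
  tb$Y_DAo <- pmin(tb$Y_DAo, tb$Y_UV - 0.03)  # venous above arterial
  tb$Y_arterial <- .clamp(add_var(mu$Y_arterial, bsd$Y_arterial,
                                  wsd$Y_arterial), 0.5, 0.98)
  tb$Y_UtA <- tb$Y_arterial
  tb$Hb_maternal <- .clamp(add_var(mu$Hb_maternal, bsd$Hb_maternal,
                                   wsd$Hb_maternal), 40, 160)
  tb$Hb_fetal <- .clamp(add_var(mu$Hb_fetal, bsd$Hb_fetal, wsd$Hb_fetal),
                        40, 160)
  tb$maternal_weight <- rep(
    .clamp(stats::rnorm(n, mu$maternal_weight, bsd$maternal_weight), 35, 95),
    each = k)
  tb$MAP <- add_var(mu$MAP, bsd$MAP, wsd$MAP) + design$effects$MAP * is_tad
  tb$HR <- add_var(mu$HR, bsd$HR, wsd$HR)
  tad1 <- tb$state == "TAD1"; tad2 <- tb$state == "TAD2"
  tb$tadalafil <- 0
  tb$tadalafil[tad1] <- pmax(stats::rnorm(sum(tad1), mu$tadalafil_TAD1,
                                          bsd$tadalafil_TAD1), 10)
  tb$tadalafil[tad2] <- pmax(stats::rnorm(sum(tad2), mu$tadalafil_TAD2,
                                          bsd$tadalafil_TAD2), 10)
  tb
}

# vessel geometry used by the cine simulations (radius mm, venc cm/s)
.vessel_geometry <- list(
  AAo = list(radius_mm = 10, venc = 150, pixel_mm = 1.0),
  UtA_left = list(radius_mm = 3.5, venc = 150, pixel_mm = 0.5),
  UtA_right = list(radius_mm = 3.5, venc = 150, pixel_mm = 0.5),
  UV = list(radius_mm = 4.5, venc = 100, pixel_mm = 0.5))

#' Simulate a full cohort
#'
#' Generates a synthetic study with known ground truth. At
#' `level = "records"` the per-animal, per-state true haemodynamic values
#' themselves are returned as the measured records (no imaging layer) —
#' the fast path for statistical simulations. At `level = "images"` each
#' record additionally receives a placentome diffusion-relaxation volume,
#' T2-prepared series for the umbilical vein, fetal descending aorta and
#' uterine artery, and phase-contrast cine simulations for the ascending
#' aorta, both uterine arteries and the umbilical vein, all with noise —
#' the inputs the measurement pipeline consumes.
#'
#' @param design A [cohort_design()].
#' @param seed RNG seed (integer).
#' @param level `"records"` or `"images"`.
#' @return A list with `truth` (ground-truth table), and for
#'   `level = "images"` also `images`: a list per animal-state holding
#'   `placentome` (from [simulate_placentome()]), `t2prep` (list per
#'   vessel) and `cine` (list per vessel).
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1,
                            level = c("records", "images")) {
  level <- match.arg(level)
  set.seed(seed)
  truth <- .simulate_truth(design)
  out <- list(truth = truth, design = design, seed = seed)
  if (level == "records") return(out)

  grid <- default_grid()
  dims <- design$placentome_dim
  lab <- array(1L, dims)
  imgs <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    p <- decide_params(f = row$f, d = row$d, d_star = row$d_star,
                       T2fb = row$T2fb, v = row$v, S0 = 100)
    plac <- simulate_placentome(list(p), lab, grid,
                                noise_spec("rician", design$image_snr))
    t2l <- list()
    for (ves in c("UV", "DAo", "UtA")) {
      Y <- switch(ves, UV = row$Y_UV, DAo = row$Y_DAo, UtA = row$Y_UtA)
      t2l[[ves]] <- simulate_t2prep(
        t2_from_so2(Y, design$calibration), S0 = 100,
        noise = noise_spec("rician", design$t2prep_snr), vessel_label = ves)
    }
    cines <- list()
    flows <- c(AAo = row$LVCO, UtA_left = row$Q_UtA / 2,
               UtA_right = row$Q_UtA / 2, UV = row$Q_UV)
    for (ves in names(.vessel_geometry)) {
      g <- .vessel_geometry[[ves]]
      area_cm2 <- pi * (g$radius_mm / 10)^2
      vmax <- 2 * (flows[[ves]] / 60) / area_cm2   # parabolic peak
      # vessel-appropriate VENC: raised above the default when the peak
      # velocity (incl. waveform modulation) would otherwise alias
      venc <- max(g$venc, 1.3 * vmax)
      cines[[ves]] <- simulate_pc_cine(
        "parabolic", vmax = vmax, radius_mm = g$radius_mm, venc = venc,
        pixel_mm = g$pixel_mm, n_phases = design$n_phases,
        waveform_amp = 0.2)
      cines[[ves]]$series$vessel_label <- ves
    }
    imgs[[i]] <- list(placentome = plac, t2prep = t2l, cine = cines)
  }
  out$images <- imgs
  out
}
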