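#' Reference band table of radiation-responsive infrared biomarkers
#'
#' Sixteen absorption bands of murine stratum corneum with their
#' radiation-exposure responses, used both as the effect-size configuration
#' of the synthetic generator and as the nominal peak positions for
#' second-derivative peak extraction. Positions are band centres in cm^-1;
#' `delta_intensity` is the exposure-induced change of the second-derivative
#' peak intensity in units of 1e-4 (on the amide-II-normalized absorbance
#' scale); `direction` says whether the band intensity goes up or down after
#' exposure. Two bands shift position after exposure: the ester carbonyl
#' (1735 -> 1743 cm^-1) and the asymmetric O-P-O stretch (1236 -> 1240
#' cm^-1); for these `position` is the control-group centre. Directions for
#' the 1336 and 1024 cm^-1 bands are not constrained by the biology encoded
#' here and default to "up".
#'
#' `amplitude` (control-group band amplitude, absorbance units) and `sigma`
#' (Gaussian width; FWHM = 2.355 sigma, 16-28 cm^-1) are generator choices,
#' not measured values: amide II is scaled to ~1 so that the amide-II peak
#' normalization is approximately the identity and injected second-derivative
#' effects land on the 1e-4 scale.
#'
#' @return A tibble with columns `peak_number`, `position`, `direction`,
#'   `shift_to` (NA when the band does not move), `delta_intensity`,
#'   `amplitude`, `sigma`, `assignment`.
#' @examples
#' synth_band_table()
#' @export
synth_band_table <- function() {
  tibble::tribble(
    ~peak_number, ~position, ~direction, ~shift_to, ~delta_intensity, ~amplitude, ~sigma, ~assignment,
    1L, 2922, "up",   NA,     0.3, 0.60, 12, "nu_as(C-H) of saturated methylene >CH2 in lipids, proteins",
    2L, 2851, "up",   NA,     0.4, 0.45, 12, "nu_s(C-H) of saturated methylene >CH2 in lipids, proteins",
    3L, 1735, "up",   1743,   0.5, 0.25,  9, "nu(C=O) of acyl groups in saturated esters (e.g. triacylglycerol)",
    4L, 1691, "up",   NA,     0.2, 0.45,  7, "nu(C=O), nu(C-N) of amide I; beta-turns",
    5L, 1648, "down", NA,     1.1, 1.30,  7, "nu(C=O), nu(C-N) of amide I; random coils",
    6L, 1626, "up",   NA,     1.5, 0.75,  7, "nu(C=O), nu(C-N) of amide I; beta-sheets",
    7L, 1553, "down", NA,     0.9, 1.00,  9, "delta(N-H), nu(C-N) of amide II",
    8L, 1518, "down", NA,     0.3, 0.30,  8, "tyrosine ring stretching (-C-C/-C=C)",
    9L, 1458, "up",   NA,     0.8, 0.40,  8, "delta(C-H) of CH3, CH2 in proteins, lipids",
    10L, 1402, "up",  NA,     0.6, 0.28,  8, "nu(COO-) in proteins, lipids",
    11L, 1336, "up",  NA,     0.3, 0.20,  8, "delta(C-H) of CH2 side chains in proteins",
    12L, 1236, "up",  1240,   0.2, 0.35,  8, "nu_as(O-P-O) of nucleic acids, phosphoproteins, phospholipids",
    13L, 1172, "down", NA,    0.1, 0.20,  8, "nu(-CH2OH), delta/nu(-C-O-) of Ser, Thr, Tyr",
    14L, 1083, "down", NA,    0.5, 0.38,  8, "nu_s(O-P-O) of nucleic acids, phosphoproteins, phospholipids",
    15L, 1024, "up",  NA,     0.1, 0.25,  8, "nu(C-O) of carbohydrate side chains of proteins",
    16L, 972,  "up",  NA,     0.1, 0.15,  8, "trans C=C bonds"
  )
}

#' Configuration of the synthetic ATR-FPA cohort generator
#'
#' Describes the study design (doses, sampling days, animals per group), the
#' detector geometry and spectral axis, the biomolecular band model, the
#' radiation effect model, and all nuisance components (baseline, CO2
#' contamination, dead pixels, noise, inter-animal variation). Identical
#' `(config, seed)` pairs generate bit-identical cohorts.
#'
#' @param n_mice_per_group animals per dose group.
#' @param doses absorbed doses in Gy; 0 is the sham control.
#' @param days days post-exposure at which maps are acquired.
#' @param axis_start,axis_end wavenumber range, cm^-1 (stored descending).
#' @param n_points spectral points per pixel.
#' @param n_rows,n_cols detector geometry (native FPA: 128 x 128).
#' @param band_table band model; see [synth_band_table()].
#' @param shift_pairs list of `c(control, treated)` band-centre pairs (cm^-1)
#'   that move after exposure; the default is taken from `band_table`.
#' @param dose_response `"flat"` (any dose > 0 triggers the full effect,
#'   the threshold-like response seen in vivo) or `"linear"` (effect scales
#'   with dose / max dose).
#' @param day_effect_profile named vector mapping day to an effect
#'   multiplier; the default peaks at day 14 and decays towards day 90,
#'   mirroring the epidermal-turnover time course.
#' @param noise_sd i.i.d. additive Gaussian noise per spectral point
#'   (absorbance units).
#' @param hetero_coef heteroscedastic noise coefficient: the per-point noise
#'   s.d. is `noise_sd * (1 + hetero_coef * A / max(A))`; 0 switches the
#'   term off.
#' @param baseline_params list with `coefs` (quadratic polynomial in the
#'   normalized axis position) and `scatter` (amplitude of a smooth
#'   1/wavenumber scattering term).
#' @param dead_pixel_rate fraction of detector pixels that record (almost)
#'   no signal.
#' @param co2_amplitude mean amplitude of the atmospheric CO2 band
#'   (2300-2400 cm^-1) added per pixel.
#' @param animal_effect_sd s.d. of the per-animal, per-band multiplicative
#'   amplitude jitter (each animal's band amplitudes are scaled by
#'   independent `1 + N(0, sd)` factors, shared across all of that animal's
#'   maps). A global per-animal scale would cancel under amide-II peak
#'   normalization; band-wise jitter is what survives the pipeline and
#'   creates genuine inter-animal variation.
#' @param pixel_scale_sd s.d. of the per-pixel multiplicative amplitude
#'   jitter (contact-quality variation).
#' @param test_fraction fraction of mice per group assigned to the held-out
#'   test split (split at the animal level, never the map level).
#' @param reference_band centre (cm^-1) of the band that sets the amide-II
#'   normalization maximum; its own amplitude effect is not injected (it is
#'   unidentifiable under peak normalization) and all effect sizes are
#'   expressed relative to it.
#' @param seed integer master seed for the cohort.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_mice_per_group = 2L,
                         doses = c(0, 0.1, 0.5, 1, 2),
                         days = c(5L, 14L, 21L, 49L, 90L),
                         axis_start = 3900,
                         axis_end = 900,
                         n_points = 4096L,
                         n_rows = 128L,
                         n_cols = 128L,
                         band_table = synth_band_table(),
                         shift_pairs = NULL,
                         dose_response = c("flat", "linear"),
                         day_effect_profile = c(`5` = 0.5, `14` = 1.0,
                                                `21` = 0.9, `49` = 0.7,
                                                `90` = 0.4),
                         noise_sd = 0.004,
                         hetero_coef = 0.1,
                         baseline_params = list(coefs = c(0.02, 0.015, 0.01),
                                                scatter = 0.01),
                         dead_pixel_rate = 0.01,
                         co2_amplitude = 0.03,
                         animal_effect_sd = 0.006,
                         pixel_scale_sd = 0.03,
                         test_fraction = 0.4,
                         reference_band = 1553,
                         seed = 1L) {
  dose_response <- match.arg(dose_response)
  if (length(doses) == 0L || length(days) == 0L) {
    stop("`doses` and `days` must be non-empty", call. = FALSE)
  }
  if (axis_start <= axis_end) stop("`axis_start` must exceed `axis_end`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (dead_pixel_rate < 0 || dead_pixel_rate >= 1) {
    stop("`dead_pixel_rate` must be in [0, 1)", call. = FALSE)
  }
  if (is.null(shift_pairs)) {
    sh <- band_table[!is.na(band_table$shift_to), ]
    shift_pairs <- purrr::map2(sh$position, sh$shift_to, c)
  }
  pos_all <- c(band_table$position,
               unlist(shift_pairs, use.names = FALSE))
  if (any(pos_all > axis_start | pos_all < axis_end)) {
    stop("all band positions must lie within the spectral axis range", call. = FALSE)
  }
  structure(list(
    n_mice_per_group = as.integer(n_mice_per_group),
    doses = doses, days = as.integer(days),
    axis_start = axis_start, axis_end = axis_end,
    n_points = as.integer(n_points),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    band_table = band_table, shift_pairs = shift_pairs,
    dose_response = dose_response,
    day_effect_profile = day_effect_profile,
    noise_sd = noise_sd, hetero_coef = hetero_coef,
    baseline_params = baseline_params,
    dead_pixel_rate = dead_pixel_rate,
    co2_amplitude = co2_amplitude,
    animal_effect_sd = animal_effect_sd,
    pixel_scale_sd = pixel_scale_sd,
    test_fraction = test_fraction,
    reference_band = reference_band,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @method print synth_config
#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d mice/group x %d doses x %d days; %dx%d pixels, %d points [%g..%g]; seed %d\n",
    x$n_mice_per_group, length(x$doses), length(x$days),
    x$n_rows, x$n_cols, x$n_points, x$axis_start, x$axis_end, x$seed
  ))
  invisible(x)
}

#' Wavenumber axis of a synthetic configuration
#' @param config a [synth_config()].
#' @return Descending numeric vector of length `n_points`.
#' @export
synth_axis <- function(config) {
  seq(config$axis_start, config$axis_end, length.out = config$n_points)
}

# deterministic small-integer stream seeds derived from a master seed
sub_seed <- function(seed, tag) {
  h <- 5381
  for (ch in utf8ToInt(paste0(tag))) h <- (h * 33 + ch) %% 2147483562
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

day_multiplier <- function(config, day) {
  m <- config$day_effect_profile[as.character(day)]
  if (is.na(m)) 1 else unname(m)
}

dose_multiplier <- function(config, dose) {
  if (dose <= 0) return(0)
  switch(config$dose_response,
         flat = 1,
         linear = dose / max(config$doses))
}

# Treated/control band parameters (centres + amplitudes) for a condition.
# Exposure changes the second-derivative peak intensity by
# delta_intensity * 1e-4 * day multiplier (* dose multiplier); for a
# Gaussian band g(x) = A exp(-(x-c)^2 / (2 s^2)) the second derivative at
# the centre is -A/s^2, so the amplitude change that produces a
# second-derivative change of delta is delta * s^2.
band_params <- function(config, dose, day) {
  bt <- config$band_table
  eff <- dose_multiplier(config, dose) * day_multiplier(config, day)
  centre <- bt$position
  amp <- bt$amplitude
  if (eff > 0) {
    sgn <- ifelse(bt$direction == "up", 1, -1)
    # The amide-II normalization reference band cannot carry its own
    # amplitude effect: dividing by the window maximum makes the reference
    # intensity unidentifiable, and injecting it would instead rescale
    # every other band. Its table row is kept for peak extraction, but the
    # generator expresses all effects relative to the reference.
    ref <- bt$position == config$reference_band
    amp <- amp + ifelse(ref, 0, sgn * bt$delta_intensity * 1e-4 * bt$sigma^2 * eff)
    for (sp in config$shift_pairs) {
      centre[centre == sp[1]] <- sp[2]
    }
  }
  list(centre = centre, amp = pmax(amp, 0), sigma = bt$sigma)
}

gaussian_mixture <- function(axis, centre, amp, sigma) {
  out <- numeric(length(axis))
  for (i in seq_along(centre)) {
    out <- out + amp[i] * exp(-(axis - centre[i])^2 / (2 * sigma[i]^2))
  }
  out
}

synth_baseline <- function(config, axis) {
  u <- (axis - config$axis_end) / (config$axis_start - config$axis_end)
  cf <- config$baseline_params$coefs
  cf[1] + cf[2] * u + cf[3] * u^2 +
    config$baseline_params$scatter * (config$axis_end / axis)
}

#' Generate one synthetic pixel spectrum
#'
#' The deterministic part is an analytic Gaussian band mixture at the band
#' table positions plus a smooth baseline; exposure (dose > 0) perturbs band
#' amplitudes by the table's second-derivative effect sizes scaled by the
#' day-profile multiplier (and the dose multiplier under a linear
#' dose-response) and moves the shifting bands to their treated centres.
#' Noise is drawn from the current RNG state; with `noise_sd = 0` the output
#' is the closed-form band-plus-baseline sum.
#'
#' @param config a [synth_config()].
#' @param dose dose in Gy (must be one of `config$doses`).
#' @param day day post-exposure (must be one of `config$days`).
#' @param animal_offset per-animal amplitude jitter: band amplitudes are
#'   scaled by `1 + animal_offset` (scalar, or one value per band-table
#'   row).
#' @param axis optionally precomputed [synth_axis()].
#' @return Numeric absorbance vector of length `config$n_points`.
#' @examples
#' cfg <- synth_config(n_points = 512L, noise_sd = 0)
#' s <- generate_spectrum(cfg, dose = 0, day = 14)
#' @export
generate_spectrum <- function(config, dose, day, animal_offset = 0,
                              axis = synth_axis(config)) {
  if (!dose %in% config$doses) stop("`dose` not in config$doses", call. = FALSE)
  if (!day %in% config$days) stop("`day` not in config$days", call. = FALSE)
  bp <- band_params(config, dose, day)
  sig <- gaussian_mixture(axis, bp$centre, bp$amp * (1 + animal_offset), bp$sigma)
  out <- sig + synth_baseline(config, axis)
  if (config$noise_sd > 0) {
    sdv <- config$noise_sd * (1 + config$hetero_coef * sig / max(sig))
    out <- out + stats::rnorm(length(axis), sd = sdv)
  }
  out
}

animal_offset_for <- function(config, mouse_id) {
  with_seed(sub_seed(config$seed, paste0("animal:", mouse_id)),
            stats::rnorm(nrow(config$band_table), sd = config$animal_effect_sd))
}

#' Generate one synthetic hyperspectral map
#'
#' Builds the full detector cube for one (mouse, dose, day) acquisition:
#' per-pixel amplitude jitter around the animal's spectrum, a per-pixel
#' atmospheric CO2 band (2300-2400 cm^-1), additive noise, and dead pixels
#' (spectra multiplied by a factor < 0.05) placed uniformly at random at
#' rate `dead_pixel_rate`. Fully determined by `(config, dose, day,
#' mouse_id, seed)`.
#'
#' @inheritParams generate_spectrum
#' @param mouse_id animal identifier (drives the per-animal random effect,
#'   which is shared across all of that animal's maps).
#' @param seed integer seed for this map's pixel-level randomness.
#' @param split split label copied into the metadata.
#' @return A [hyperspec_map()] with populated metadata.
#' @export
generate_map <- function(config, dose, day, mouse_id = "M001", seed = config$seed,
                         split = NA_character_) {
  if (!dose %in% config$doses) stop("`dose` not in config$doses", call. = FALSE)
  if (!day %in% config$days) stop("`day` not in config$days", call. = FALSE)
  axis <- synth_axis(config)
  n_pix <- config$n_rows * config$n_cols
  n_pts <- config$n_points
  bp <- band_params(config, dose, day)
  a_off <- animal_offset_for(config, mouse_id)
  base_bands <- gaussian_mixture(axis, bp$centre, bp$amp * (1 + a_off), bp$sigma)
  baseline <- synth_baseline(config, axis)
  co2_profile <- exp(-(axis - 2350)^2 / (2 * 18^2))
  co2_profile[axis < 2300 - 60 | axis > 2400 + 60] <- 0

  flat <- with_seed(seed, {
    scale <- 1 + stats::rnorm(n_pix, sd = config$pixel_scale_sd)
    co2 <- config$co2_amplitude * stats::runif(n_pix, 0.5, 1.5)
    flat <- tcrossprod(scale, base_bands)
    flat <- flat + rep(baseline, each = n_pix)
    flat <- flat + tcrossprod(co2, co2_profile)
    if (config$noise_sd > 0) {
      sdv <- config$noise_sd * (1 + config$hetero_coef * base_bands / max(base_bands))
      flat <- flat + matrix(stats::rnorm(n_pix * n_pts), n_pix, n_pts) *
        rep(sdv, each = n_pix)
    }
    if (config$dead_pixel_rate > 0) {
      n_dead <- stats::rbinom(1, n_pix, config$dead_pixel_rate)
      if (n_dead > 0) {
        dead <- sample.int(n_pix, n_dead)
        flat[dead, ] <- flat[dead, , drop = FALSE] *
          stats::runif(n_dead, 0, 0.05)
      }
    }
    flat
  })

  hyperspec_map(
    array(flat, dim = c(config$n_rows, config$n_cols, n_pts)),
    axis,
    list(sample_id = sprintf("%s_d%02d", mouse_id, day),
         mouse_id = mouse_id, strain = "C57BL/6J",
         dose_gy = dose, day = as.integer(day), split = split)
  )
}

#' Generate a full synthetic cohort
#'
#' One map per (mouse, day); each mouse carries exactly one dose for the
#' whole study. The train/test split is assigned at the animal level
#' (`test_fraction` of the mice in every dose group), so no mouse
#' contributes maps to both splits.
#'
#' @param config a [synth_config()].
#' @return A list with `maps` (named list of [hyperspec_map()]s) and `meta`
#'   (tibble: `sample_id`, `mouse_id`, `strain`, `dose_gy`, `day`, `split`).
#' @examples
#' cfg <- synth_config(n_mice_per_group = 1L, doses = c(0, 1), days = 14L,
#'                     n_rows = 8L, n_cols = 8L, n_points = 256L)
#' coh <- generate_cohort(cfg)
#' nrow(coh$meta)
#' @export
generate_cohort <- function(config) {
  if (config$n_mice_per_group < 1L) {
    stop("`n_mice_per_group` must be >= 1", call. = FALSE)
  }
  design <- tidyr::expand_grid(
    dose_gy = config$doses,
    mouse_in_group = seq_len(config$n_mice_per_group)
  )
  design$mouse_id <- sprintf("M%03d", seq_len(nrow(design)))
  n_test <- max(1L, round(config$test_fraction * config$n_mice_per_group))
  if (config$n_mice_per_group == 1L) n_test <- 0L
  design <- design |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::mutate(split = {
      k <- dplyr::n()
      test_idx <- with_seed(
        sub_seed(config$seed, paste0("split:", .data$dose_gy[1])),
        sample.int(k, min(n_test, k))
      )
      ifelse(seq_len(k) %in% test_idx, "test", "train")
    }) |>
    dplyr::ungroup()

  grid <- tidyr::expand_grid(design, day = config$days)
  maps <- purrr::pmap(
    list(grid$dose_gy, grid$mouse_id, grid$day, grid$split),
    function(dose, mouse, day, split) {
      generate_map(config, dose, day, mouse,
                   seed = sub_seed(config$seed, sprintf("map:%s:%d", mouse, day)),
                   split = split)
    }
  )
  names(maps) <- vapply(maps, function(m) m$meta$sample_id, "")
  meta <- tibble::tibble(
    sample_id = names(maps),
    mouse_id = grid$mouse_id,
    strain = "C57BL/6J",
    dose_gy = grid$dose_gy,
    day = as.integer(grid$day),
    split = grid$split
  )
  list(maps = maps, meta = meta)
}
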