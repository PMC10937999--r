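#' Pixel quality-control parameters
#'
#' A detector pixel is kept only if (1) its amide signal-to-noise ratio is at
#' least `snr_threshold` and (2) the ratio of its amide signal to the
#' atmospheric CO2 signal (2300-2400 cm^-1) is at least
#' `co2_ratio_threshold`. Images retaining more than `pixel_cap` pixels are
#' then capped to the `pixel_cap` quietest ones (lowest noise level).
#'
#' The "amide signal" is the maximum absorbance in the amide I window (the
#' dominant protein band); the noise level is the standard deviation of the
#' spectrum in a spectrally quiet window between the amide and CO2 regions.
#' Both window choices are configurable (e.g. `amide_window = c(1480, 1590)`
#' for amide II, `noise_stat = "peak_to_peak"`).
#'
#' @param snr_threshold minimum amide signal / noise ratio (default 200).
#' @param co2_ratio_threshold minimum amide / CO2 signal ratio (default 15).
#' @param pixel_cap maximum pixels retained per image (default 100).
#' @param amide_window,co2_window,noise_window closed wavenumber intervals
#'   (cm^-1).
#' @param noise_stat `"sd"` or `"peak_to_peak"`.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(snr_threshold = 200,
                      co2_ratio_threshold = 15,
                      pixel_cap = 100L,
                      amide_window = c(1600, 1700),
                      co2_window = c(2300, 2400),
                      noise_window = c(1800, 2300),
                      noise_stat = c("sd", "peak_to_peak")) {
  noise_stat <- match.arg(noise_stat)
  stopifnot(snr_threshold > 0, co2_ratio_threshold > 0, pixel_cap >= 1)
  structure(list(
    snr_threshold = snr_threshold,
    co2_ratio_threshold = co2_ratio_threshold,
    pixel_cap = as.integer(pixel_cap),
    amide_window = amide_window, co2_window = co2_window,
    noise_window = noise_window, noise_stat = noise_stat
  ), class = "qc_params")
}

#' Per-spectrum QC signals
#'
#' `amide_signal()` is the maximum absorbance in the amide window;
#' `co2_signal()` the maximum in the CO2 window; `noise_level()` the
#' standard deviation (or peak-to-peak range) in the noise window.
#'
#' @param spectrum numeric absorbance vector.
#' @param axis wavenumber vector.
#' @param params a [qc_params()].
#' @return A scalar absorbance value.
#' @examples
#' ax <- seq(3900, 900, length.out = 1024)
#' s <- exp(-(ax - 1648)^2 / 200)
#' amide_signal(s, ax, qc_params())
#' @export
amide_signal <- function(spectrum, axis, params = qc_params()) {
  sb <- slice_band(spectrum, axis, params$amide_window[1], params$amide_window[2])
  max(sb$values)
}

#' @rdname amide_signal
#' @export
co2_signal <- function(spectrum, axis, params = qc_params()) {
  sb <- slice_band(spectrum, axis, params$co2_window[1], params$co2_window[2])
  max(sb$values)
}

#' @rdname amide_signal
#' @export
noise_level <- function(spectrum, axis, params = qc_params()) {
  sb <- slice_band(spectrum, axis, params$noise_window[1], params$noise_window[2])
  if (length(sb$values) < 3L) {
    stop("noise window covers fewer than 3 spectral points", call. = FALSE)
  }
  switch(params$noise_stat,
         sd = stats::sd(sb$values),
         peak_to_peak = diff(range(sb$values)))
}

# vectorized over a flattened pixel matrix [n_pix, n_points]
qc_stats_matrix <- function(flat, axis, params) {
  am <- slice_band(flat, axis, params$amide_window[1], params$amide_window[2])
  co <- slice_band(flat, axis, params$co2_window[1], params$co2_window[2])
  nw <- slice_band(flat, axis, params$noise_window[1], params$noise_window[2])
  noise <- if (params$noise_stat == "sd") {
    apply(nw$values, 1L, stats::sd)
  } else {
    apply(nw$values, 1L, function(v) diff(range(v)))
  }
  list(
    amide = apply(am$values, 1L, max),
    co2 = apply(co$values, 1L, max),
    noise = noise
  )
}

#' Quality-control mask for one hyperspectral map
#'
#' Applies both per-pixel filters. Degenerate denominators pass rather than
#' reject: a CO2 signal below `1e-12` makes the CO2 ratio +Inf (absence of
#' contaminant should not reject a pixel), and a noise level below `1e-12`
#' with positive amide signal makes the SNR +Inf. A dead pixel (amide signal
#' ~ 0) fails the SNR test.
#'
#' @param map a [hyperspec_map()]; QC runs on raw spectra by default
#'   (matching an acquisition-order workflow where QC precedes
#'   pretreatment), but any map — raw or preprocessed — is accepted.
#' @param params a [qc_params()].
#' @return A [pixel_mask()] with provenance `"qc"` and attribute `"stats"`
#'   (tibble of per-pixel amide, CO2 and noise values).
#' @export
qc_mask <- function(map, params = qc_params()) {
  d <- dim(map$absorbance)
  flat <- matrix(map$absorbance, d[1L] * d[2L], d[3L])
  st <- qc_stats_matrix(flat, map$axis, params)
  eps <- 1e-12
  snr <- ifelse(st$noise <= eps, ifelse(st$amide > 0, Inf, 0),
                st$amide / st$noise)
  co2r <- ifelse(st$co2 <= eps, Inf, st$amide / st$co2)
  acc <- snr >= params$snr_threshold & co2r >= params$co2_ratio_threshold
  mask <- pixel_mask(matrix(acc, d[1L], d[2L]), "qc")
  attr(mask, "stats") <- tibble::tibble(
    row = rep(seq_len(d[1L]), times = d[2L]),
    col = rep(seq_len(d[2L]), each = d[1L]),
    amide = st$amide, co2 = st$co2, noise = st$noise,
    snr = snr, co2_ratio = co2r
  )
  mask
}

#' Cap a QC mask at the quietest pixels
#'
#' When an image retains more than `pixel_cap` pixels after [qc_mask()], only
#' the `pixel_cap` pixels with the lowest noise level are preserved (the
#' quieter the better); images at or below the cap keep all accepted pixels.
#' Ties at the cap boundary are broken by (row, col) lexicographic order.
#'
#' @param map a [hyperspec_map()].
#' @param mask the [qc_mask()] of `map` (its `"stats"` attribute is reused
#'   when present).
#' @param params a [qc_params()].
#' @return A [pixel_mask()] with provenance `"qc_capped"`.
#' @export
rank_and_cap <- function(map, mask, params = qc_params()) {
  acc <- mask$accepted
  n_acc <- sum(acc)
  if (n_acc <= params$pixel_cap) {
    out <- pixel_mask(acc, "qc_capped")
    attr(out, "n_accepted_raw") <- n_acc
    return(out)
  }
  st <- attr(mask, "stats")
  if (is.null(st)) {
    d <- dim(map$absorbance)
    flat <- matrix(map$absorbance, d[1L] * d[2L], d[3L])
    noise <- qc_stats_matrix(flat, map$axis, params)$noise
    st <- tibble::tibble(
      row = rep(seq_len(d[1L]), times = d[2L]),
      col = rep(seq_len(d[2L]), each = d[1L]),
      noise = noise
    )
  }
  cand <- st[as.vector(acc), c("row", "col", "noise")]
  ord <- order(cand$noise, cand$row, cand$col)
  keep <- cand[ord[seq_len(params$pixel_cap)], ]
  sel <- matrix(FALSE, nrow(acc), ncol(acc))
  sel[cbind(keep$row, keep$col)] <- TRUE
  out <- pixel_mask(sel, "qc_capped")
  attr(out, "n_accepted_raw") <- n_acc
  out
}

#' Run QC over a cohort
#'
#' Convenience wrapper: [qc_mask()] + [rank_and_cap()] per map, with a
#' per-image accounting table. Images retaining zero pixels are reported and
#' later dropped from classification.
#'
#' @param maps named list of [hyperspec_map()]s.
#' @param params a [qc_params()].
#' @return A list with `masks` (named list of capped masks) and `summary`
#'   (tibble: `sample_id`, `n_accepted_raw`, `n_retained`).
#' @export
qc_cohort <- function(maps, params = qc_params()) {
  masks <- purrr::map(maps, function(m) {
    rank_and_cap(m, qc_mask(m, params), params)
  })
  summary <- tibble::tibble(
    sample_id = names(maps),
    n_accepted_raw = vapply(masks, function(mk) {
      as.integer(attr(mk, "n_accepted_raw") %||% sum(mk$accepted))
    }, 1L),
    n_retained = vapply(masks, function(mk) sum(mk$accepted), 1L)
  )
  list(masks = masks, summary = summary)
}
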