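#' Spectral pretreatment parameters
#'
#' Configuration of the five-step pretreatment pipeline applied to every
#' hyperspectral map before analysis: (1) spectral range clipping, (2)
#' dead-pixel filling by spatial mean, (3) spatial median denoising, (4)
#' rubber-band baseline correction, (5) amide-II peak normalization.
#'
#' @param clip_window closed wavenumber interval kept after clipping
#'   (default `[900, 3600]` cm^-1 — the outer ends of the recorded range
#'   carry high variance and are discarded).
#' @param fill_kernel odd spatial kernel size of the dead-pixel mean filter.
#' @param median_kernel odd spatial kernel size of the median denoiser.
#' @param dead_threshold a pixel is dead when its total absorbance falls
#'   below this fraction of the image's median total absorbance.
#' @param baseline_anchors wavenumber control points of the rubber-band
#'   baseline; each is snapped to the spectrum's minimum within
#'   `anchor_halfwidth` of the nominal position.
#' @param anchor_halfwidth snap window half-width, cm^-1.
#' @param amide2_window amide II normalization window (default
#'   `[1480, 1590]` cm^-1).
#' @param baseline_before_denoise set `TRUE` to run baseline correction
#'   before the median denoiser (the two orders are both defensible; the
#'   default follows clip -> fill -> denoise -> baseline -> normalize).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(clip_window = c(900, 3600),
                              fill_kernel = 5L,
                              median_kernel = 5L,
                              dead_threshold = 0.1,
                              baseline_anchors = c(3600, 2750, 1800, 900),
                              anchor_halfwidth = 25,
                              amide2_window = c(1480, 1590),
                              baseline_before_denoise = FALSE) {
  stopifnot(fill_kernel %% 2 == 1, fill_kernel >= 3,
            median_kernel %% 2 == 1, median_kernel >= 3,
            dead_threshold > 0, anchor_halfwidth > 0,
            length(baseline_anchors) >= 2)
  if (any(baseline_anchors < clip_window[1] | baseline_anchors > clip_window[2])) {
    stop("all `baseline_anchors` must lie inside `clip_window`", call. = FALSE)
  }
  structure(list(
    clip_window = clip_window,
    fill_kernel = as.integer(fill_kernel),
    median_kernel = as.integer(median_kernel),
    dead_threshold = dead_threshold,
    baseline_anchors = sort(baseline_anchors, decreasing = TRUE),
    anchor_halfwidth = anchor_halfwidth,
    amide2_window = amide2_window,
    baseline_before_denoise = baseline_before_denoise
  ), class = "preprocess_params")
}

#' Clip a map to the retained spectral range
#'
#' @param map a [hyperspec_map()].
#' @param params a [preprocess_params()].
#' @return The map restricted to the closed `clip_window`; idempotent.
#' @export
clip_range <- function(map, params = preprocess_params()) {
  sb <- slice_band(map, lo = params$clip_window[1], hi = params$clip_window[2])
  hyperspec_map(sb$values, sb$axis, map$meta)
}

#' Fill dead detector pixels by spatial mean
#'
#' A pixel is flagged dead when its total absorbance is below
#' `dead_threshold` times the image median total absorbance; dead pixels are
#' replaced by the mean spectrum of the non-dead pixels in their
#' `fill_kernel` x `fill_kernel` window (truncated at the image boundary).
#' Non-dead pixels are untouched.
#'
#' @inheritParams clip_range
#' @return The filled map, with the dead-pixel flags in attribute
#'   `"dead_pixels"` (logical matrix).
#' @export
fill_dead_pixels <- function(map, params = preprocess_params()) {
  d <- dim(map$absorbance)
  totals <- apply(map$absorbance, c(1, 2), sum)
  med <- stats::median(totals)
  dead <- totals < params$dead_threshold * med
  if (all(dead) || med <= 0) {
    stop("all pixels flagged dead; map unusable", call. = FALSE)
  }
  if (!any(dead)) {
    out <- map
    attr(out, "dead_pixels") <- dead
    return(out)
  }
  res <- cpp_fill_dead(as.vector(map$absorbance), d[1L], d[2L], d[3L],
                       as.vector(dead), params$fill_kernel)
  out <- hyperspec_map(array(res$cube, dim = d), map$axis, map$meta)
  attr(out, "dead_pixels") <- dead
  out
}

#' Spatial median denoising
#'
#' Each wavenumber channel is filtered independently: every pixel is
#' replaced by the median of its `median_kernel` x `median_kernel` spatial
#' neighborhood, truncated at the image boundary (no padding).
#'
#' @inheritParams clip_range
#' @return The denoised map.
#' @export
median_denoise <- function(map, params = preprocess_params()) {
  d <- dim(map$absorbance)
  out <- cpp_median_filter(as.vector(map$absorbance), d[1L], d[2L], d[3L],
                           params$median_kernel)
  hyperspec_map(array(out, dim = d), map$axis, map$meta)
}

anchor_windows <- function(axis_asc, anchors, halfwidth) {
  lo <- integer(length(anchors))
  hi <- integer(length(anchors))
  for (i in seq_along(anchors)) {
    idx <- which(axis_asc >= anchors[i] - halfwidth &
                   axis_asc <= anchors[i] + halfwidth)
    if (length(idx) == 0L) {
      stop(sprintf("baseline anchor %g cm^-1 lies outside the axis", anchors[i]),
           call. = FALSE)
    }
    lo[i] <- min(idx) - 1L
    hi[i] <- max(idx) - 1L
  }
  ord <- order(lo)
  list(lo = lo[ord], hi = hi[ord])
}

rubberband_matrix <- function(flat, axis, params) {
  # cpp_rubberband wants strictly ascending x
  n <- length(axis)
  rev_idx <- n:1
  asc <- axis[rev_idx]
  w <- anchor_windows(asc, params$baseline_anchors, params$anchor_halfwidth)
  # the axis endpoints are mandatory support points (degenerate windows), so
  # the baseline spans the whole spectrum instead of extending as a constant
  lo <- c(w$lo, 0L, n - 1L)
  hi <- c(w$hi, 0L, n - 1L)
  ord <- order(lo)
  base_asc <- cpp_rubberband(flat[, rev_idx, drop = FALSE], asc,
                             lo[ord], hi[ord])
  base_asc[, rev_idx, drop = FALSE]
}

#' Rubber-band baseline correction
#'
#' The baseline is a piecewise-linear curve through support points obtained
#' by snapping each anchor wavenumber to the spectrum's minimum within
#' `anchor_halfwidth`, augmented by the lower convex hull of the spectrum
#' between consecutive support points; the two axis endpoints are always
#' support points, so the baseline spans the full spectrum. The corrected
#' spectrum (spectrum - baseline) is exactly zero at every support point and
#' non-negative wherever the hull touches; on a convex spectrum (e.g. a pure
#' linear baseline) the correction is exact.
#'
#' @param spectrum numeric absorbance vector.
#' @param axis wavenumber vector (descending).
#' @param params a [preprocess_params()].
#' @return A list with `baseline` and `corrected`, both along `axis`.
#' @examples
#' ax <- seq(3600, 900, length.out = 512)
#' s <- 0.2 + 1e-4 * ax + exp(-(ax - 1650)^2 / 200)
#' out <- rubberband_baseline(s, ax)
#' max(abs(out$corrected[abs(ax - 1650) > 200]))  # ~0 off-peak
#' @export
rubberband_baseline <- function(spectrum, axis, params = preprocess_params()) {
  base <- rubberband_matrix(matrix(spectrum, nrow = 1L), axis, params)[1L, ]
  list(baseline = base, corrected = spectrum - base)
}

#' Amide-II peak normalization
#'
#' Divides a (baseline-corrected) spectrum by its maximum absorbance in the
#' amide II window, so the normalized maximum in that window is exactly 1.
#'
#' @inheritParams rubberband_baseline
#' @return The normalized spectrum.
#' @export
normalize_amide2 <- function(spectrum, axis, params = preprocess_params()) {
  sb <- slice_band(spectrum, axis, params$amide2_window[1], params$amide2_window[2])
  m <- max(sb$values)
  if (!is.finite(m) || m <= 0) {
    stop(structure(class = c("radsig_degenerate_pixel", "error", "condition"),
                   list(message = "amide II maximum <= 0; degenerate pixel",
                        call = NULL)))
  }
  spectrum / m
}

#' Full pretreatment pipeline for one map
#'
#' Composition, in order: [clip_range()] -> [fill_dead_pixels()] ->
#' [median_denoise()] -> [rubberband_baseline()] (per pixel) ->
#' [normalize_amide2()] (per pixel). Pixels whose amide II maximum is not
#' positive after baseline correction cannot be normalized; they are left
#' as zeros and flagged invalid rather than aborting the map.
#'
#' @inheritParams clip_range
#' @return The preprocessed map with attributes `"dead_pixels"` and
#'   `"valid_pixels"` (logical matrices) recording the per-pixel flags.
#' @export
preprocess_map <- function(map, params = preprocess_params()) {
  m <- clip_range(map, params)
  m <- fill_dead_pixels(m, params)
  dead <- attr(m, "dead_pixels")
  if (params$baseline_before_denoise) {
    m <- baseline_stage(m, params)
    m <- median_denoise(m, params)
  } else {
    m <- median_denoise(m, params)
    m <- baseline_stage(m, params)
  }
  d <- dim(m$absorbance)
  flat <- matrix(m$absorbance, d[1L] * d[2L], d[3L])
  sb <- slice_band(flat, m$axis, params$amide2_window[1], params$amide2_window[2])
  norm <- apply(sb$values, 1L, max)
  valid <- is.finite(norm) & norm > 0
  flat[valid, ] <- flat[valid, , drop = FALSE] / norm[valid]
  flat[!valid, ] <- 0
  out <- hyperspec_map(array(flat, dim = d), m$axis, m$meta)
  attr(out, "dead_pixels") <- dead
  attr(out, "valid_pixels") <- matrix(valid, d[1L], d[2L])
  out
}

baseline_stage <- function(map, params) {
  d <- dim(map$absorbance)
  flat <- matrix(map$absorbance, d[1L] * d[2L], d[3L])
  base <- rubberband_matrix(flat, map$axis, params)
  hyperspec_map(array(flat - base, dim = d), map$axis, map$meta)
}
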