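#' Savitzky-Golay derivative parameters
#'
#' Defaults: window of 5 points, cubic polynomial, second derivative — the
#' standard setting for second-derivative band sharpening (the window must
#' exceed the polynomial order, which must be at least the derivative
#' order).
#'
#' @param window_length odd filter window (points).
#' @param polyorder local polynomial degree.
#' @param deriv_order derivative order (2 for band sharpening).
#' @return A list of class `deriv_params`.
#' @export
deriv_params <- function(window_length = 5L, polyorder = 3L, deriv_order = 2L) {
  stopifnot(window_length %% 2 == 1)
  if (!(window_length > polyorder && polyorder >= deriv_order)) {
    stop("need window_length > polyorder >= deriv_order", call. = FALSE)
  }
  structure(list(window_length = as.integer(window_length),
                 polyorder = as.integer(polyorder),
                 deriv_order = as.integer(deriv_order)),
            class = "deriv_params")
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Differentiates with respect to wavenumber using the actual axis spacing
#' (not index units), so intensities are comparable across clip settings.
#' Sign convention: an absorbance maximum in the original spectrum produces
#' a minimum of the second derivative at the same position. Edge samples
#' where the filter window is truncated are returned as `NA` rather than
#' extrapolated.
#'
#' @param spectrum numeric absorbance vector (or matrix, one spectrum per
#'   row).
#' @param axis wavenumber vector; must be uniformly spaced (tolerance 1e-6
#'   relative).
#' @param params a [deriv_params()].
#' @return The derivative spectrum (same shape as input), `NA` at the
#'   truncated edges.
#' @examples
#' ax <- seq(2000, 1000, length.out = 501)
#' d2 <- second_derivative(3 * ax^2, ax)
#' d2[250]  # = 6
#' @export
second_derivative <- function(spectrum, axis, params = deriv_params()) {
  dx <- diff(axis)
  if (max(abs(dx - dx[1])) > 1e-6 * abs(dx[1])) {
    stop("axis must be uniformly spaced for Savitzky-Golay differentiation",
         call. = FALSE)
  }
  h <- (params$window_length - 1L) %/% 2L
  apply_one <- function(v) {
    out <- signal::sgolayfilt(v, p = params$polyorder, n = params$window_length,
                              m = params$deriv_order, ts = abs(dx[1]))
    out[seq_len(h)] <- NA_real_
    out[seq(length(out) - h + 1L, length(out))] <- NA_real_
    out
  }
  if (is.matrix(spectrum)) {
    t(apply(spectrum, 1L, apply_one))
  } else {
    apply_one(spectrum)
  }
}

#' Group mean spectra over a pixel pool
#'
#' @param pool pixel-pool tibble (see [pool_pixels()]).
#' @param group column name (string) to group by, e.g. `"exposed"` or
#'   `"dose_gy"`.
#' @return A tibble with one row per group: the grouping value and a matrix
#'   column `spectrum` holding the arithmetic mean over pixels; the axis
#'   attribute is carried over.
#' @export
group_mean_spectra <- function(pool, group = "exposed") {
  stopifnot(group %in% names(pool), nrow(pool) > 0)
  vals <- unique(pool[[group]])
  means <- purrr::map(vals, function(v) {
    rows <- pool[[group]] == v
    if (!any(rows)) stop("empty group", call. = FALSE)
    colMeans(pool$spectrum[rows, , drop = FALSE])
  })
  out <- tibble::tibble(.group = vals,
                        n_pixels = vapply(vals, function(v) sum(pool[[group]] == v), 1L),
                        spectrum = do.call(rbind, means))
  names(out)[1L] <- group
  attr(out, "axis") <- pool_axis(pool)
  out
}

#' Difference spectrum (treated minus control)
#'
#' @param mean_treated,mean_control numeric spectra on the same axis.
#' @param negate multiply by -1 (a display convention that flips deepened
#'   second-derivative minima upward; quantitative analysis uses the
#'   un-negated difference).
#' @return The difference spectrum.
#' @export
difference_spectrum <- function(mean_treated, mean_control, negate = FALSE) {
  if (length(mean_treated) != length(mean_control)) {
    stop("spectra must share one axis", call. = FALSE)
  }
  d <- mean_treated - mean_control
  if (negate) -d else d
}

#' Locate second-derivative band minima near nominal positions
#'
#' For each record, searches the second-derivative spectrum for its local
#' minimum within `search_halfwidth` of the nominal band position. The band
#' intensity is the value at the minimum; `peak_to_peak` is the mean of the
#' two flanking local maxima minus the minimum (the more baseline-robust
#' statistic). Records with no interior local minimum in the window are
#' flagged `found = FALSE`.
#'
#' @param d2 second-derivative spectrum (vector along `axis`).
#' @param axis wavenumber vector.
#' @param records tibble with at least `position` (defaults to the built-in
#'   band table).
#' @param search_halfwidth search window half-width, cm^-1.
#' @return A tibble: `peak_number`, `nominal_cm1`, `found`, `found_cm1`,
#'   `intensity`, `peak_to_peak`.
#' @export
peak_minima <- function(d2, axis, records = synth_band_table(),
                        search_halfwidth = 10) {
  stopifnot(all(records$position <= max(axis) & records$position >= min(axis)))
  n <- length(d2)
  is_min <- c(FALSE, d2[2:(n - 1)] < d2[1:(n - 2)] & d2[2:(n - 1)] <= d2[3:n], FALSE)
  is_max <- c(FALSE, d2[2:(n - 1)] > d2[1:(n - 2)] & d2[2:(n - 1)] >= d2[3:n], FALSE)
  is_min[is.na(is_min)] <- FALSE
  is_max[is.na(is_max)] <- FALSE
  one <- function(pos) {
    win <- which(axis >= pos - search_halfwidth & axis <= pos + search_halfwidth)
    cand <- win[is_min[win]]
    if (length(cand) == 0L) {
      return(tibble::tibble(found = FALSE, found_cm1 = NA_real_,
                            intensity = NA_real_, peak_to_peak = NA_real_))
    }
    i_min <- cand[which.min(d2[cand])]
    left_max <- rev(which(is_max[seq_len(i_min - 1L)]))
    right_max <- which(is_max)
    right_max <- right_max[right_max > i_min]
    flank <- c(if (length(left_max)) d2[left_max[1]] else NA_real_,
               if (length(right_max)) d2[right_max[1]] else NA_real_)
    tibble::tibble(found = TRUE, found_cm1 = axis[i_min],
                   intensity = d2[i_min],
                   peak_to_peak = mean(flank, na.rm = TRUE) - d2[i_min])
  }
  res <- purrr::map(records$position, one) |> dplyr::bind_rows()
  tibble::tibble(
    peak_number = records$peak_number %||% seq_len(nrow(records)),
    nominal_cm1 = records$position,
    res
  )
}

#' Exposure-induced band position shift
#'
#' Signed shift (treated minimum position minus control minimum position)
#' of one band's second-derivative minimum.
#'
#' @param control_d2,treated_d2 second-derivative spectra on `axis`.
#' @param axis wavenumber vector.
#' @param position nominal band position, cm^-1 (control-group centre).
#' @param search_halfwidth search window half-width, cm^-1.
#' @return Shift in cm^-1.
#' @export
peak_shift <- function(control_d2, treated_d2, axis, position,
                       search_halfwidth = 10) {
  rec <- tibble::tibble(peak_number = 1L, position = position)
  ctl <- peak_minima(control_d2, axis, rec, search_halfwidth)
  trt <- peak_minima(treated_d2, axis, rec, search_halfwidth)
  if (!ctl$found || !trt$found) {
    stop(sprintf("no local minimum near %g cm^-1 in one of the groups", position),
         call. = FALSE)
  }
  trt$found_cm1 - ctl$found_cm1
}

#' Tabulate the exposure difference across all reference bands
#'
#' Convenience report mirroring the biomarker table: mean second-derivative
#' spectra per group, their difference at each band minimum, and the
#' detected positions.
#'
#' @param pool preprocessed pixel pool with an `exposed` column.
#' @param records band records (default [synth_band_table()]).
#' @param params a [deriv_params()].
#' @param search_halfwidth search window half-width, cm^-1.
#' @return A tibble with per-band control/treated intensities,
#'   `delta_intensity_1e4` (treated - control, x 1e-4 units) and
#'   `shift_cm1`.
#' @export
band_difference_table <- function(pool, records = synth_band_table(),
                                  params = deriv_params(),
                                  search_halfwidth = 10) {
  gm <- group_mean_spectra(pool, "exposed")
  axis <- attr(gm, "axis")
  ctl <- second_derivative(gm$spectrum[gm$exposed == 0, ], axis, params)
  trt <- second_derivative(gm$spectrum[gm$exposed == 1, ], axis, params)
  pc <- peak_minima(ctl, axis, records, search_halfwidth)
  pt <- peak_minima(trt, axis, records, search_halfwidth)
  tibble::tibble(
    peak_number = pc$peak_number,
    nominal_cm1 = pc$nominal_cm1,
    control_cm1 = pc$found_cm1,
    treated_cm1 = pt$found_cm1,
    control_intensity = pc$intensity,
    treated_intensity = pt$intensity,
    delta_intensity_1e4 = (pt$intensity - pc$intensity) / 1e-4,
    shift_cm1 = pt$found_cm1 - pc$found_cm1
  )
}
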