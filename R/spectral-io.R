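#' Construct a hyperspectral ATR-FTIR map
#'
#' The atomic input of the pipeline: one sample's absorbance cube recorded by
#' a focal-plane-array (FPA) detector, together with its wavenumber axis and
#' sample metadata. The native detector geometry is 128 x 128 pixels; other
#' sizes are accepted (useful for fixtures) but flagged with a `native_fpa`
#' attribute.
#'
#' @param absorbance numeric 3-D array `[rows, cols, n_points]`.
#' @param axis numeric wavenumber vector (cm^-1), strictly decreasing, of
#'   length `n_points`. Spectra are stored high-to-low wavenumber
#'   (3900 -> 900 cm^-1), the acquisition order of the instrument.
#' @param meta named list (or one-row data frame) with at least `sample_id`;
#'   conventional fields are `mouse_id`, `strain`, `dose_gy`, `day`, `split`.
#' @return An object of class `hyperspec_map`: a list with elements
#'   `absorbance`, `axis`, `meta`.
#' @examples
#' ax <- seq(3900, 900, length.out = 64)
#' cube <- array(runif(4 * 4 * 64), dim = c(4, 4, 64))
#' m <- hyperspec_map(cube, ax, list(sample_id = "s1"))
#' dim(m$absorbance)
#' @export
hyperspec_map <- function(absorbance, axis, meta = list(sample_id = "sample")) {
  if (!is.array(absorbance) || length(dim(absorbance)) != 3L) {
    stop("`absorbance` must be a 3-D array [rows, cols, n_points]", call. = FALSE)
  }
  axis <- as.numeric(axis)
  if (length(axis) != dim(absorbance)[3L]) {
    stop(sprintf(
      "axis length (%d) does not match spectral dimension of cube (%d)",
      length(axis), dim(absorbance)[3L]
    ), call. = FALSE)
  }
  if (any(diff(axis) >= 0)) {
    stop("wavenumber axis must be strictly decreasing (stored 3900 -> 900 cm^-1)",
         call. = FALSE)
  }
  if (is.data.frame(meta)) meta <- as.list(meta[1L, , drop = FALSE])
  if (is.null(meta$sample_id)) stop("meta must contain `sample_id`", call. = FALSE)
  structure(
    list(absorbance = absorbance, axis = axis, meta = meta),
    native_fpa = all(dim(absorbance)[1:2] == c(128L, 128L)),
    class = "hyperspec_map"
  )
}

#' @method print hyperspec_map
#' @export
print.hyperspec_map <- function(x, ...) {
  d <- dim(x$absorbance)
  cat(sprintf(
    "<hyperspec_map> %s: %d x %d pixels, %d points [%.1f .. %.1f cm^-1]%s\n",
    x$meta$sample_id, d[1], d[2], d[3], x$axis[1], x$axis[length(x$axis)],
    if (isTRUE(attr(x, "native_fpa"))) "" else " (non-native geometry)"
  ))
  if (!is.null(x$meta$dose_gy)) {
    cat(sprintf("  dose %.1f Gy, day %s, mouse %s\n",
                x$meta$dose_gy, x$meta$day %||% "?", x$meta$mouse_id %||% "?"))
  }
  invisible(x)
}

#' @export
dim.hyperspec_map <- function(x) dim(x$absorbance)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Native focal-plane-array geometry
#'
#' The imaging geometry of the ATR-FPA setup this pipeline targets: a
#' 128 x 128 detector imaging a ~64 x 64 um field through the ATR
#' objective, giving 16,384 spectra per image at a nominal pixel size of
#' 0.5 um.
#'
#' @param n_pixels_side detector side length in pixels.
#' @param image_side_um imaged field side length in micrometres.
#' @return A one-row tibble: `n_pixels_side`, `image_side_um`,
#'   `n_spectra` and `pixel_size_um`.
#' @examples
#' fpa_geometry()
#' @export
fpa_geometry <- function(n_pixels_side = 128L, image_side_um = 64) {
  n <- as.integer(n_pixels_side)
  tibble::tibble(
    n_pixels_side = n,
    image_side_um = image_side_um,
    n_spectra = n * n,
    pixel_size_um = image_side_um / n
  )
}

#' Write / read a hyperspectral map on disk
#'
#' Maps are persisted as a self-describing directory: `meta.json` (metadata
#' plus array shape), `wavenumbers.txt` (one value per line, printed with 17
#' significant digits so doubles round-trip exactly) and `absorbance.bin`
#' (little-endian IEEE doubles in R's native column-major order). The
#' round trip `read_map(write_map(m))` is bit-exact for the cube, the axis
#' and the metadata.
#'
#' @param map a [hyperspec_map()].
#' @param path directory to create (write) or read.
#' @return `write_map()` returns `path` invisibly; `read_map()` returns a
#'   `hyperspec_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "hyperspec_map"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    format = "radsig-map",
    version = 1L,
    shape = dim(map$absorbance),
    meta = map$meta
  )
  jsonlite::write_json(header, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(sprintf("%.17g", map$axis), file.path(path, "wavenumbers.txt"))
  con <- file(file.path(path, "absorbance.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(map$absorbance), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta_path <- file.path(path, "meta.json")
  wn_path <- file.path(path, "wavenumbers.txt")
  abs_path <- file.path(path, "absorbance.bin")
  if (!file.exists(meta_path)) {
    stop(sprintf("map format error: missing 'meta.json' under %s", path), call. = FALSE)
  }
  header <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(header$format, "radsig-map")) {
    stop("map format error: 'meta.json' does not declare format 'radsig-map'",
         call. = FALSE)
  }
  if (!file.exists(wn_path)) {
    stop("map format error: missing dataset 'wavenumbers'", call. = FALSE)
  }
  if (!file.exists(abs_path)) {
    stop("map format error: missing dataset 'absorbance'", call. = FALSE)
  }
  shape <- as.integer(header$shape)
  axis <- as.numeric(readLines(wn_path))
  if (length(axis) != shape[3L]) {
    stop(sprintf(
      "map format error: 'wavenumbers' length %d does not match declared spectral dimension %d",
      length(axis), shape[3L]
    ), call. = FALSE)
  }
  con <- file(abs_path, "rb")
  on.exit(close(con))
  n <- prod(shape)
  vals <- readBin(con, what = "double", n = n + 1L, size = 8L, endian = "little")
  if (length(vals) != n) {
    stop(sprintf(
      "map format error: 'absorbance' holds %d values, expected %d", length(vals), n
    ), call. = FALSE)
  }
  meta <- header$meta
  # JSON has no integer/double distinction; restore the canonical types
  if (!is.null(meta$dose_gy)) meta$dose_gy <- as.numeric(meta$dose_gy)
  if (!is.null(meta$day)) meta$day <- as.integer(meta$day)
  hyperspec_map(array(vals, dim = shape), axis, meta)
}

#' Slice a spectral band (closed interval in wavenumber)
#'
#' The single source of truth for spectral windowing: every windowed
#' computation in the package (QC signals, amide-II normalization, feature
#' ranges, embedding band) selects points through this function. Selection is
#' the closed interval `lo <= axis <= hi`; axis order (descending) is
#' preserved.
#'
#' @param x a `hyperspec_map`, a numeric spectrum, or a matrix of spectra
#'   (one row per pixel, columns along the axis).
#' @param axis wavenumber vector; taken from `x` when `x` is a map.
#' @param lo,hi band edges in cm^-1, `lo < hi` (equal for a single point).
#' @return A list with elements `values` (same shape class as the input,
#'   restricted to the band) and `axis` (the selected wavenumbers), plus
#'   `index` (the selected positions in the original axis).
#' @examples
#' ax <- seq(3900, 900, length.out = 301)
#' s <- exp(-(ax - 1650)^2 / 500)
#' sb <- slice_band(s, ax, 1600, 1700)
#' range(sb$axis)
#' @export
slice_band <- function(x, axis = NULL, lo, hi) {
  if (inherits(x, "hyperspec_map")) {
    axis <- x$axis
    values <- x$absorbance
  } else {
    if (is.null(axis)) stop("`axis` is required unless `x` is a hyperspec_map", call. = FALSE)
    values <- x
  }
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) == 0L) {
    stop(sprintf("band [%g, %g] cm^-1 has empty overlap with axis [%g, %g]",
                 lo, hi, min(axis), max(axis)), call. = FALSE)
  }
  vals <- if (is.array(values) && length(dim(values)) == 3L) {
    values[, , idx, drop = FALSE]
  } else if (is.matrix(values)) {
    values[, idx, drop = FALSE]
  } else {
    values[idx]
  }
  list(values = vals, axis = axis[idx], index = idx)
}

#' Flatten maps and masks into a pixel pool
#'
#' A pixel pool is the tabular form the classification stages work on: one
#' row per retained pixel, carrying its provenance (`sample_id`, `row`,
#' `col`), its sample metadata and its full spectrum as a matrix column
#' named `spectrum` (columns ordered along the shared wavenumber axis).
#'
#' @param maps list of `hyperspec_map`s sharing one axis.
#' @param masks optional list of [pixel_mask()]s parallel to `maps`; when
#'   `NULL` every pixel is pooled.
#' @return A tibble with columns `sample_id`, `mouse_id`, `strain`,
#'   `dose_gy`, `day`, `split`, `row`, `col`, `exposed` and the matrix
#'   column `spectrum`; the shared axis is stored in attribute `"axis"`
#'   (retrieve with [pool_axis()]).
#' @export
pool_pixels <- function(maps, masks = NULL) {
  stopifnot(length(maps) >= 1L)
  axis <- maps[[1L]]$axis
  for (m in maps) {
    if (!isTRUE(all.equal(m$axis, axis))) {
      stop("all maps in a pool must share the same wavenumber axis", call. = FALSE)
    }
  }
  if (!is.null(masks) && length(masks) != length(maps)) {
    stop("`masks` must be parallel to `maps`", call. = FALSE)
  }
  pieces <- purrr::map2(maps, seq_along(maps), function(m, i) {
    d <- dim(m$absorbance)
    acc <- if (is.null(masks)) {
      matrix(TRUE, d[1L], d[2L])
    } else {
      stopifnot(all(dim(masks[[i]]$accepted) == d[1:2]))
      masks[[i]]$accepted
    }
    keep <- which(acc)  # column-major order: col-by-col, row fastest
    if (length(keep) == 0L) return(NULL)
    rows <- ((keep - 1L) %% d[1L]) + 1L
    cols <- ((keep - 1L) %/% d[1L]) + 1L
    flat <- matrix(m$absorbance, d[1L] * d[2L], d[3L])
    spec <- flat[keep, , drop = FALSE]
    colnames(spec) <- sprintf("%.4f", axis)
    meta <- m$meta
    tibble::tibble(
      sample_id = as.character(meta$sample_id),
      mouse_id = as.character(meta$mouse_id %||% NA_character_),
      strain = as.character(meta$strain %||% NA_character_),
      dose_gy = as.numeric(meta$dose_gy %||% NA_real_),
      day = as.integer(meta$day %||% NA_integer_),
      split = as.character(meta$split %||% NA_character_),
      row = rows,
      col = cols,
      exposed = as.integer(dose_gy > 0),
      spectrum = spec
    )
  })
  pool <- dplyr::bind_rows(pieces)
  attr(pool, "axis") <- axis
  pool
}

#' Wavenumber axis attached to a pixel pool
#' @param pool a tibble produced by [pool_pixels()] (or a filtered copy —
#'   the attribute survives dplyr verbs that keep attributes; when absent it
#'   is reconstructed from the `spectrum` column names).
#' @return numeric wavenumber vector.
#' @export
pool_axis <- function(pool) {
  ax <- attr(pool, "axis")
  if (is.null(ax)) ax <- as.numeric(colnames(pool$spectrum))
  ax
}

#' Export a pixel pool to CSV
#'
#' One row per pixel; spectra as wide columns named `wn_<wavenumber>`.
#' @param pool pixel-pool tibble.
#' @param path output file.
#' @export
write_pool_csv <- function(pool, path) {
  flat <- dplyr::select(pool, -"spectrum")
  spec <- as.data.frame(pool$spectrum)
  names(spec) <- paste0("wn_", colnames(pool$spectrum))
  utils::write.csv(cbind(as.data.frame(flat), spec), path, row.names = FALSE)
  invisible(path)
}

#' Boolean detector mask
#'
#' @param accepted logical matrix `[rows, cols]`, `TRUE` = pixel kept.
#' @param provenance short label recording which stage produced the mask
#'   (`"qc"`, `"center"`, `"pacmap"`, or an intersection label).
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(accepted, provenance = "qc") {
  stopifnot(is.matrix(accepted), is.logical(accepted))
  structure(list(accepted = accepted, provenance = provenance),
            class = "pixel_mask")
}

#' @method print pixel_mask
#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %s: %d / %d accepted\n",
              x$provenance, sum(x$accepted), length(x$accepted)))
  invisible(x)
}

#' Intersect detector masks
#' @param ... `pixel_mask` objects of identical shape.
#' @return A `pixel_mask` accepted where all inputs accept.
#' @export
mask_intersect <- function(...) {
  ms <- list(...)
  acc <- Reduce(`&`, lapply(ms, `[[`, "accepted"))
  pixel_mask(acc, paste(vapply(ms, `[[`, "", "provenance"), collapse = "+"))
}
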