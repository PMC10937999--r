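#' Center-region pixel mask
#'
#' The simple comparison arm to embedding-based pixel selection: accept only
#' the central `size` x `size` window of the detector. For the native
#' 128 x 128 array and `size = 21` this is rows and columns 53-73 inclusive
#' (0-based; offset `floor((128 - 21) / 2)`).
#'
#' @param n_rows,n_cols detector geometry.
#' @param size side of the central square window.
#' @return A [pixel_mask()] with provenance `"center"`.
#' @export
center_region_mask <- function(n_rows = 128L, n_cols = 128L, size = 21L) {
  stopifnot(size >= 1, size <= n_rows, size <= n_cols)
  acc <- matrix(FALSE, n_rows, n_cols)
  r0 <- (n_rows - size) %/% 2L
  c0 <- (n_cols - size) %/% 2L
  acc[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size)] <- TRUE
  pixel_mask(acc, "center")
}

#' Embed pooled pixels in two dimensions on the amide band
#'
#' Pixels are embedded using the 1500-1700 cm^-1 band, which carries the
#' dominant amide I/II structure. The embedding backend is pluggable behind
#' a fixed contract (seeded, deterministic, 2-D coordinates); the default
#' backend is principal-component scores of the band slice, which is exactly
#' deterministic. The contract also attaches a per-pixel mean kNN distance
#' in the embedding, the outlier score used by [outlier_mask()].
#'
#' @param pool pixel-pool tibble (normally preprocessed).
#' @param band wavenumber interval used for embedding.
#' @param seed integer seed (consumed by stochastic backends; the PCA
#'   backend is seed-invariant but the argument is part of the contract).
#' @param k neighbors for the kNN outlier score.
#' @param backend `"pca"` or a function `(matrix, seed) -> [n, 2] matrix`.
#' @return An object of class `radsig_embedding`: a list with `coords`
#'   `[n_pixels, 2]`, `pixel_index` (tibble `sample_id`, `row`, `col`),
#'   `knn_distance`, and `accepted` (all `TRUE` until [outlier_mask()] is
#'   applied).
#' @export
embed_pixels <- function(pool, band = c(1500, 1700), seed = 1L, k = 20L,
                         backend = "pca") {
  if (nrow(pool) < 10L) {
    stop("embedding undefined for fewer than 10 pixels", call. = FALSE)
  }
  sb <- slice_band(pool$spectrum, pool_axis(pool), band[1], band[2])
  x <- sb$values
  coords <- if (is.function(backend)) {
    backend(x, seed)
  } else {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
    s <- p$x
    if (ncol(s) < 2L) s <- cbind(s, 0)
    s[, 1:2, drop = FALSE]
  }
  if (!all(is.finite(coords))) stop("embedding produced non-finite coordinates", call. = FALSE)
  kk <- min(k, nrow(coords) - 1L)
  knn_dist <- knn_mean_distance(coords, kk)
  structure(list(
    coords = unname(coords),
    pixel_index = dplyr::select(pool, "sample_id", "row", "col"),
    knn_distance = knn_dist,
    accepted = rep(TRUE, nrow(coords))
  ), class = "radsig_embedding")
}

# mean distance to the k nearest neighbours, computed in row blocks so the
# full distance matrix is never materialized
knn_mean_distance <- function(coords, k, block = 512L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1L, function(dr) {
      mean(sqrt(sort(dr, partial = k)[seq_len(k)]))
    })
  }
  out
}

#' @method print radsig_embedding
#' @export
print.radsig_embedding <- function(x, ...) {
  cat(sprintf("<radsig_embedding> %d pixels, %d accepted (%.2f%%)\n",
              length(x$accepted), sum(x$accepted),
              100 * mean(x$accepted)))
  invisible(x)
}

#' Reject embedding outliers by kNN-distance percentile
#'
#' A pixel is rejected when its mean distance to its k nearest embedding
#' neighbors exceeds the given percentile of that score's distribution
#' across all pixels. The rejected set is regrouped into one
#' accepted/rejected detector mask per sample. On well-formed data the
#' default percentile (99.5) rejects at most ~0.5% of pixels, keeping over
#' 99% on the manifold.
#'
#' @param emb a [embed_pixels()] result.
#' @param percentile rejection threshold percentile in (0, 100]; 100 accepts
#'   everything.
#' @param n_rows,n_cols detector geometry for the per-sample masks.
#' @return A list with `emb` (the embedding with `accepted` updated) and
#'   `masks` (named list of [pixel_mask()]s, provenance `"pacmap"`, one per
#'   sample; pixels absent from the pool are rejected in these masks).
#' @export
outlier_mask <- function(emb, percentile = 99.5, n_rows = 128L, n_cols = 128L) {
  stopifnot(inherits(emb, "radsig_embedding"))
  if (percentile <= 0 || percentile > 100) {
    stop("`percentile` must be in (0, 100]", call. = FALSE)
  }
  thr <- stats::quantile(emb$knn_distance, percentile / 100, names = FALSE,
                         type = 7)
  emb$accepted <- emb$knn_distance <= thr
  idx <- emb$pixel_index
  masks <- purrr::map(split(seq_len(nrow(idx)), idx$sample_id), function(rows) {
    acc <- matrix(FALSE, n_rows, n_cols)
    kept <- rows[emb$accepted[rows]]
    acc[cbind(idx$row[kept], idx$col[kept])] <- TRUE
    pixel_mask(acc, "pacmap")
  })
  list(emb = emb, masks = masks)
}
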