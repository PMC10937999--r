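#' Feature specification for pixel-level classification
#'
#' Classification features are the preprocessed absorbance values inside the
#' fingerprint range (900-1800 cm^-1) and the C-H stretching range
#' (2800-3050 cm^-1), concatenated per pixel. Column order is descending
#' wavenumber within each range, ranges in the listed order.
#'
#' @param ranges list of closed wavenumber intervals, cm^-1.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(ranges = list(c(900, 1800), c(2800, 3050))) {
  stopifnot(length(ranges) >= 1)
  structure(list(ranges = ranges, source = "preprocessed"),
            class = "feature_spec")
}

#' Build the feature matrix and labels from a pixel pool
#'
#' @param pool preprocessed pixel-pool tibble with `dose_gy`.
#' @param spec a [feature_spec()].
#' @param label `"binary"` (exposed = dose > 0) or `"dose"` (multi-class).
#' @return A list with `x` (matrix, one row per pixel, columns named by
#'   wavenumber), `y` (integer 0/1 for binary, factor for dose),
#'   `wavenumber` (numeric per column), and `pool_info` (tibble of
#'   `sample_id`, `mouse_id`, `dose_gy`, `day`, `split`).
#' @export
build_features <- function(pool, spec = feature_spec(),
                           label = c("binary", "dose")) {
  label <- match.arg(label)
  axis <- pool_axis(pool)
  pieces <- purrr::map(spec$ranges, function(r) {
    slice_band(pool$spectrum, axis, r[1], r[2])
  })
  x <- do.call(cbind, purrr::map(pieces, "values"))
  wn <- unlist(purrr::map(pieces, "axis"), use.names = FALSE)
  colnames(x) <- sprintf("%.4f", wn)
  y <- if (label == "binary") as.integer(pool$dose_gy > 0) else factor(pool$dose_gy)
  list(x = x, y = y, wavenumber = wn,
       pool_info = dplyr::select(
         pool, dplyr::any_of(c("sample_id", "mouse_id", "dose_gy", "day", "split"))))
}

#' Classifier specification
#'
#' The five supported model families: L1- and L2-penalized logistic
#' regression (`lasso_lr`, `ridge_lr`), a support vector machine (`svm`), a
#' fully-connected net (`fcnn`) and a one-dimensional convolutional net
#' (`cnn1d`). Penalty strengths for the penalized regressions are selected
#' on a validation split carved out of the training samples — never on the
#' test set.
#'
#' @param family one of `"lasso_lr"`, `"ridge_lr"`, `"svm"`, `"fcnn"`,
#'   `"cnn1d"`.
#' @param penalty fixed penalty strength (lambda for glmnet, cost for the
#'   SVM); `NULL` selects lambda on the validation split (glmnet families)
#'   or uses cost 1 (SVM).
#' @param hidden hidden-layer widths of the fully-connected net.
#' @param arch 1D-CNN architecture: parallel vectors `kernels`, `channels`,
#'   `strides` for the convolution blocks (ReLU after each), followed by
#'   global average pooling and one dense output unit.
#' @param epochs,batch_size,lr net-training hyperparameters.
#' @param validation_fraction fraction of training *samples* held out for
#'   penalty selection.
#' @param kernel SVM kernel.
#' @param seed seed for initialization, shuffling and validation carving.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("lasso_lr", "ridge_lr", "svm", "fcnn", "cnn1d"),
                       penalty = NULL,
                       hidden = c(128L, 32L),
                       arch = list(kernels = c(9L, 7L), channels = c(8L, 16L),
                                   strides = c(3L, 3L)),
                       epochs = 30L, batch_size = 64L, lr = 1e-3,
                       validation_fraction = 0.2,
                       kernel = "linear",
                       seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, penalty = penalty, hidden = hidden,
                 arch = arch, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 validation_fraction = validation_fraction,
                 kernel = kernel, seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a pixel-level classifier
#'
#' @param spec a [model_spec()].
#' @param x feature matrix (from [build_features()]).
#' @param y binary labels (0/1 integer) — at least two classes required.
#' @param sample_id optional per-row sample identifiers; used to carve the
#'   validation split at the sample level when selecting penalties.
#' @return An object of class `radsig_model` holding the fitted model, the
#'   spec, and the feature wavenumbers.
#' @export
train_model <- function(spec, x, y, sample_id = NULL) {
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  y <- as.integer(y)
  fit <- switch(
    spec$family,
    lasso_lr = fit_glmnet(spec, x, y, alpha = 1, sample_id = sample_id),
    ridge_lr = fit_glmnet(spec, x, y, alpha = 0, sample_id = sample_id),
    svm = fit_svm(spec, x, y),
    fcnn = train_net(x, y, "mlp", hidden = spec$hidden, epochs = spec$epochs,
                     batch_size = spec$batch_size, lr = spec$lr, seed = spec$seed),
    cnn1d = train_net(x, y, "cnn", arch = spec$arch, epochs = spec$epochs,
                      batch_size = spec$batch_size, lr = spec$lr, seed = spec$seed)
  )
  structure(list(spec = spec, fit = fit,
                 wavenumber = as.numeric(colnames(x)),
                 n_train = nrow(x)),
            class = "radsig_model")
}

fit_glmnet <- function(spec, x, y, alpha, sample_id = NULL) {
  if (!is.null(spec$penalty)) {
    return(list(kind = "glmnet",
                model = glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                                       lambda = spec$penalty),
                lambda = spec$penalty))
  }
  # lambda selected on a validation split carved from training (at the
  # sample level when sample ids are supplied), then refit on all rows
  units <- if (is.null(sample_id)) seq_len(nrow(x)) else sample_id
  uniq <- unique(units)
  val_units <- with_seed(spec$seed, {
    sample(uniq, max(1L, round(spec$validation_fraction * length(uniq))))
  })
  val <- units %in% val_units
  if (all(val) || !any(val) ||
      length(unique(y[!val])) < 2L || length(unique(y[val])) < 2L) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha, nfolds = 5)
    return(list(kind = "glmnet",
                model = glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                                       lambda = cv$lambda.min),
                lambda = cv$lambda.min))
  }
  path <- glmnet::glmnet(x[!val, , drop = FALSE], y[!val], family = "binomial",
                         alpha = alpha)
  pv <- stats::predict(path, x[val, , drop = FALSE], type = "response")
  acc <- apply(pv, 2L, function(p) mean((p > 0.5) == y[val]))
  best <- path$lambda[which.max(acc)]
  list(kind = "glmnet",
       model = glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                              lambda = best),
       lambda = best)
}

fit_svm <- function(spec, x, y) {
  # constant columns are structural here (the normalization point is exactly
  # 1, baseline supports exactly 0); scaling them would only raise warnings
  scale_cols <- apply(x, 2L, stats::sd) > 0
  m <- with_seed(spec$seed, {
    e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = spec$kernel,
               cost = spec$penalty %||% 1, probability = TRUE,
               scale = scale_cols)
  })
  list(kind = "svm", model = m)
}

#' @method print radsig_model
#' @export
print.radsig_model <- function(x, ...) {
  cat(sprintf("<radsig_model> family %s, %d features, %d training pixels\n",
              x$spec$family, length(x$wavenumber), x$n_train))
  invisible(x)
}

#' Predict exposure probabilities for pixels
#'
#' @param object a [train_model()] fit.
#' @param newdata feature matrix with the same columns as training.
#' @param ... unused.
#' @return Numeric vector of per-pixel probabilities of the exposed class.
#' @export
predict.radsig_model <- function(object, newdata, ...) {
  fit <- object$fit
  if (!is.null(fit$kind) && fit$kind == "glmnet") {
    as.vector(stats::predict(fit$model, newdata, type = "response"))
  } else if (!is.null(fit$kind) && fit$kind == "svm") {
    pr <- stats::predict(fit$model, newdata, probability = TRUE)
    attr(pr, "probabilities")[, "1"]
  } else {
    predict_net(fit, newdata)
  }
}

#' Wavenumbers selected by the LASSO logistic regression
#'
#' @param model a `radsig_model` with family `lasso_lr`.
#' @return A tibble of nonzero-coefficient wavenumbers sorted by decreasing
#'   `abs(coefficient)`; empty when everything was shrunk to zero.
#' @export
lasso_selected_wavenumbers <- function(model) {
  stopifnot(inherits(model, "radsig_model"))
  if (model$spec$family != "lasso_lr") {
    stop("wavenumber selection is defined for the lasso_lr family", call. = FALSE)
  }
  beta <- as.vector(stats::coef(model$fit$model))[-1L]  # drop intercept
  nz <- which(beta != 0)
  out <- tibble::tibble(wavenumber = model$wavenumber[nz], coefficient = beta[nz])
  dplyr::arrange(out, dplyr::desc(abs(.data$coefficient)))
}

#' Aggregate pixel predictions to sample labels by majority vote
#'
#' A sample is called exposed when more than half of its pixels are
#' predicted exposed; the positive-vote fraction doubles as the sample's
#' continuous score for ROC analysis. An exact tie predicts unexposed under
#' the default (conservative) tie rule.
#'
#' @param pixel_pred tibble with columns `sample_id` and `pixel_label`
#'   (0/1).
#' @param tie_rule `"negative"` or `"positive"`.
#' @return A tibble: `sample_id`, `n_pixels`, `n_positive`, `vote_fraction`,
#'   `label`.
#' @export
majority_vote <- function(pixel_pred, tie_rule = c("negative", "positive")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(all(c("sample_id", "pixel_label") %in% names(pixel_pred)))
  out <- pixel_pred |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      n_positive = sum(.data$pixel_label),
      vote_fraction = .data$n_positive / .data$n_pixels,
      .groups = "drop"
    )
  out$label <- as.integer(
    if (tie_rule == "negative") out$vote_fraction > 0.5 else out$vote_fraction >= 0.5
  )
  out
}

#' Predict a pixel pool and aggregate to samples
#'
#' @param model a `radsig_model`.
#' @param pool preprocessed pixel pool.
#' @param fspec the [feature_spec()] used at training.
#' @param threshold pixel probability cut-off for the 0/1 pixel label.
#' @param tie_rule passed to [majority_vote()].
#' @return An object of class `radsig_prediction`: list with `pixels`
#'   (tibble: `sample_id`, `row`, `col`, `prob`, `pixel_label`, truth
#'   columns) and `samples` (majority-vote tibble joined with metadata:
#'   `dose_gy`, `day`, `exposed`).
#' @export
predict_pool <- function(model, pool, fspec = feature_spec(), threshold = 0.5,
                         tie_rule = "negative") {
  ft <- build_features(pool, fspec)
  prob <- predict(model, ft$x)
  pixels <- dplyr::bind_cols(
    dplyr::select(pool, dplyr::any_of(c("sample_id", "row", "col", "dose_gy",
                                        "day", "exposed"))),
    tibble::tibble(prob = prob, pixel_label = as.integer(prob > threshold))
  )
  samples <- majority_vote(pixels, tie_rule)
  meta <- pool |>
    dplyr::distinct(.data$sample_id, .data$mouse_id, .data$dose_gy, .data$day,
                    .data$exposed)
  samples <- dplyr::left_join(samples, meta, by = "sample_id")
  structure(list(pixels = pixels, samples = samples,
                 family = model$spec$family),
            class = "radsig_prediction")
}

#' @method print radsig_prediction
#' @export
print.radsig_prediction <- function(x, ...) {
  cat(sprintf("<radsig_prediction> %s: %d pixels, %d samples\n",
              x$family, nrow(x$pixels), nrow(x$samples)))
  invisible(x)
}

#' Split a pixel pool into its train and test parts
#'
#' Splitting is defined at the animal level by the `split` metadata column;
#' the function asserts that no mouse (and hence no sample) appears in both
#' parts.
#'
#' @param pool pixel-pool tibble with a `split` column.
#' @return A list with elements `train` and `test`.
#' @export
split_pool <- function(pool) {
  stopifnot("split" %in% names(pool))
  tr <- pool[pool$split == "train", ]
  te <- pool[pool$split == "test", ]
  overlap <- intersect(unique(tr$mouse_id), unique(te$mouse_id))
  if (length(overlap) > 0) {
    stop("train/test leakage: mice present in both splits: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  ax <- pool_axis(pool)
  attr(tr, "axis") <- ax
  attr(te, "axis") <- ax
  list(train = tr, test = te)
}
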