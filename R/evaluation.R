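#' Balanced accuracy
#'
#' Mean of sensitivity (true-positive rate) and specificity (true-negative
#' rate); robust to class imbalance.
#'
#' @param labels true 0/1 labels (both classes must be present).
#' @param predictions predicted 0/1 labels.
#' @return A rate in `[0, 1]`.
#' @export
balanced_accuracy <- function(labels, predictions) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(unique(labels)) < 2L) {
    stop("balanced accuracy undefined: labels contain a single class", call. = FALSE)
  }
  sens <- mean(predictions[labels == 1] == 1)
  spec <- mean(predictions[labels == 0] == 0)
  (sens + spec) / 2
}

#' Empirical ROC curve and area under it
#'
#' Standard threshold-sweep ROC on a continuous score (for samples, the
#' majority-vote fraction): tied scores are grouped into single thresholds
#' and the area is computed by the trapezoid rule.
#'
#' @param scores continuous scores, larger = more likely positive.
#' @param labels true 0/1 labels.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("ROC undefined: labels contain a single class", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n_pos <- sum(l == 1)
  n_neg <- sum(l == 0)
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Specificity at a fixed sensitivity threshold
#'
#' Chooses the largest score cut-off whose sensitivity reaches
#' `sens_threshold` (predicting positive for scores at or above the
#' cut-off) and returns the specificity there. When all scores are tied the
#' only qualifying cut-off predicts everything positive, giving
#' specificity 0.
#'
#' @inheritParams roc_and_auc
#' @param sens_threshold required sensitivity (default 0.9).
#' @return Specificity in `[0, 1]`.
#' @export
specificity_at_sensitivity <- function(scores, labels, sens_threshold = 0.9) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0L) {
    stop("no positive samples: required sensitivity is unreachable", call. = FALSE)
  }
  r <- roc_and_auc(scores, labels)
  ok <- which(r$roc$tpr >= sens_threshold)
  # thresholds are descending along the curve; the first qualifying point
  # is the largest cut-off
  1 - r$roc$fpr[ok[1]]
}

#' Permutation p-value for a sample-level metric
#'
#' Labels are permuted at the sample level (pixels within a sample stay
#' together by construction, since the metric is computed on sample-level
#' scores), and the add-one estimator
#' `p = (1 + #(permuted >= observed)) / (1 + n_perm)` is returned.
#'
#' @param metric_fn function `(labels, scores_or_predictions) -> scalar`.
#' @param labels sample-level 0/1 labels.
#' @param scores sample-level scores or predicted labels (second argument
#'   of `metric_fn`).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(metric_fn, labels, scores, n_perm = 1000L,
                               seed = 1L) {
  if (n_perm < 100L) stop("use at least 100 permutations", call. = FALSE)
  obs <- metric_fn(labels, scores)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      perm <- metric_fn(sample(labels), scores)
      if (perm >= obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
}

stratum_metrics <- function(samples, sens_thresholds) {
  la <- samples$exposed
  pr <- samples$label
  sc <- samples$vote_fraction
  r <- roc_and_auc(sc, la)
  out <- tibble::tibble(
    n_samples = nrow(samples),
    n_exposed = sum(la == 1),
    n_control = sum(la == 0),
    accuracy = mean(pr == la),
    balanced_accuracy = balanced_accuracy(la, pr),
    auc = r$auc
  )
  for (s in sens_thresholds) {
    out[[sprintf("spec_at_sens_%g", s)]] <- specificity_at_sensitivity(sc, la, s)
  }
  out
}

#' Stratified evaluation report
#'
#' Computes pixel- and sample-level accuracies, balanced accuracy, ROC/AUC
#' and specificity-at-sensitivity overall and within strata: per dose (each
#' dose stratum pools that dose's exposed samples with *all* control
#' samples) and per day (samples acquired that day). Strata lacking either
#' class are skipped with a warning.
#'
#' @param pred a [predict_pool()] result.
#' @param sens_thresholds sensitivity pins for the specificity read-outs;
#'   both the conventional 0.9 and a near-perfect 0.99 pin are reported by
#'   default.
#' @param n_perm permutations for the balanced-accuracy p-value (0 skips).
#' @param seed RNG seed for the permutation test.
#' @return An object of class `radsig_eval`: list with `overall` (one-row
#'   tibble), `by_dose`, `by_day` (tibbles), `roc` (sample-level ROC
#'   points), `permutation_p`.
#' @export
stratified_report <- function(pred, sens_thresholds = c(0.9, 0.99),
                              n_perm = 0L, seed = 1L) {
  stopifnot(inherits(pred, "radsig_prediction"))
  samples <- pred$samples
  pixels <- pred$pixels
  overall <- stratum_metrics(samples, sens_thresholds)
  overall <- dplyr::bind_cols(
    tibble::tibble(pixel_accuracy = mean(pixels$pixel_label == pixels$exposed),
                   sample_accuracy = mean(samples$label == samples$exposed)),
    overall
  )
  controls <- samples[samples$exposed == 0, ]
  by_dose <- purrr::map(
    sort(unique(samples$dose_gy[samples$exposed == 1])),
    function(d) {
      strat <- dplyr::bind_rows(samples[samples$dose_gy == d, ], controls)
      if (length(unique(strat$exposed)) < 2L) {
        warning(sprintf("dose stratum %g Gy lacks a class; skipped", d))
        return(NULL)
      }
      dplyr::bind_cols(tibble::tibble(dose_gy = d),
                       stratum_metrics(strat, sens_thresholds))
    }) |> dplyr::bind_rows()
  by_day <- purrr::map(sort(unique(samples$day)), function(dd) {
    strat <- samples[samples$day == dd, ]
    if (length(unique(strat$exposed)) < 2L) {
      warning(sprintf("day stratum %s lacks a class; skipped", dd))
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(day = dd),
                     stratum_metrics(strat, sens_thresholds))
  }) |> dplyr::bind_rows()
  perm_p <- if (n_perm > 0) {
    permutation_pvalue(function(l, p) balanced_accuracy(l, p),
                       samples$exposed, samples$label, n_perm, seed)
  } else {
    NA_real_
  }
  structure(list(
    overall = overall, by_dose = by_dose, by_day = by_day,
    roc = roc_and_auc(samples$vote_fraction, samples$exposed)$roc,
    permutation_p = perm_p, family = pred$family
  ), class = "radsig_eval")
}

#' @method print radsig_eval
#' @export
print.radsig_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<radsig_eval> %s: sample accuracy %.3f, balanced accuracy %.3f, AUC %.3f\n",
    x$family %||% "?", o$sample_accuracy, o$balanced_accuracy, o$auc))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p-value: %.4g\n", x$permutation_p))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report into one row per stratum
#'
#' @param x a `radsig_eval`.
#' @param ... unused.
#' @return A tibble with a `stratum` column (`"overall"`, `"dose:<d>"`,
#'   `"day:<d>"`) and the metric columns.
#' @export
tidy.radsig_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(stratum = "overall"),
                     dplyr::select(x$overall, -"pixel_accuracy", -"sample_accuracy")),
    if (nrow(x$by_dose)) dplyr::bind_cols(
      tibble::tibble(stratum = sprintf("dose:%g", x$by_dose$dose_gy)),
      dplyr::select(x$by_dose, -"dose_gy")),
    if (nrow(x$by_day)) dplyr::bind_cols(
      tibble::tibble(stratum = sprintf("day:%d", x$by_day$day)),
      dplyr::select(x$by_day, -"day"))
  )
}

#' @rdname tidy.radsig_eval
#' @export
glance.radsig_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(family = x$family %||% NA_character_),
                   x$overall,
                   tibble::tibble(permutation_p = x$permutation_p))
}

#' Tidy a fitted classifier
#'
#' For the penalized regressions, one row per feature with its coefficient;
#' for the SVM, the support-vector count; for the nets, one row per
#' parameter tensor.
#'
#' @param x a `radsig_model`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.radsig_model <- function(x, ...) {
  fit <- x$fit
  if (!is.null(fit$kind) && fit$kind == "glmnet") {
    beta <- as.vector(stats::coef(fit$model))
    tibble::tibble(term = c("(Intercept)", sprintf("%.4f", x$wavenumber)),
                   wavenumber = c(NA_real_, x$wavenumber),
                   estimate = beta)
  } else if (!is.null(fit$kind) && fit$kind == "svm") {
    tibble::tibble(term = "n_support_vectors",
                   estimate = as.numeric(fit$model$tot.nSV))
  } else {
    tibble::tibble(term = names(fit$params),
                   estimate = vapply(fit$params, function(p) sqrt(mean(p^2)), 0))
  }
}

#' @rdname tidy.radsig_model
#' @export
glance.radsig_model <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    n_features = length(x$wavenumber),
    n_train_pixels = x$n_train,
    penalty = if (!is.null(x$fit$lambda)) x$fit$lambda else NA_real_
  )
}
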