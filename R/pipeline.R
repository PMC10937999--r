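#' Configuration of a full pipeline run
#'
#' Bundles the per-stage configurations into one reproducible run
#' description. Every stage seed is derived deterministically from the
#' global `seed`.
#'
#' @param synth a [synth_config()] describing the cohort to simulate (or
#'   `NULL` when `maps`/`meta` are passed to [run_pipeline()] directly).
#' @param qc a [qc_params()].
#' @param preprocess a [preprocess_params()].
#' @param features a [feature_spec()].
#' @param families model families to train (subset of the five).
#' @param region_mode `"center"`, `"pacmap"` or `"both"` — how the pixel
#'   pool is selected.
#' @param label_mode `"binary"` (exposed vs control) or `"dose"`
#'   (multi-class, expected weak under a flat dose-response).
#' @param center_size side of the central detector window for the center
#'   region arm.
#' @param embed_band wavenumber interval for the embedding arm.
#' @param outlier_percentile kNN-distance rejection percentile.
#' @param epochs,batch_size net-training hyperparameters forwarded to
#'   [model_spec()].
#' @param n_perm permutations for the report's significance test (0 = off).
#' @param output_dir directory for run artifacts (`NULL` = in-memory only).
#' @param seed global run seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       qc = qc_params(),
                       preprocess = preprocess_params(),
                       features = feature_spec(),
                       families = c("lasso_lr", "ridge_lr", "svm", "fcnn", "cnn1d"),
                       region_mode = c("both", "center", "pacmap"),
                       label_mode = c("binary", "dose"),
                       center_size = 21L,
                       embed_band = c(1500, 1700),
                       outlier_percentile = 99.5,
                       epochs = 30L,
                       batch_size = 64L,
                       n_perm = 0L,
                       output_dir = NULL,
                       seed = 1L) {
  region_mode <- match.arg(region_mode)
  label_mode <- match.arg(label_mode)
  structure(list(synth = synth, qc = qc, preprocess = preprocess,
                 features = features, families = families,
                 region_mode = region_mode, label_mode = label_mode,
                 center_size = as.integer(center_size),
                 embed_band = embed_band,
                 outlier_percentile = outlier_percentile,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_perm = as.integer(n_perm),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Convenience front-end: a YAML file with optional blocks `synth`, `qc`,
#' `preprocess` and top-level fields matching [run_config()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  if (!is.null(y$qc)) args$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$preprocess)) args$preprocess <- do.call(preprocess_params, y$preprocess)
  top <- setdiff(names(y), c("synth", "qc", "preprocess"))
  args <- c(args, y[top])
  do.call(run_config, args)
}

pool_for_region <- function(maps, meta, qc_masks, valid_masks, region,
                            config) {
  masks <- purrr::imap(qc_masks, function(mk, sid) {
    mask_intersect(mk, valid_masks[[sid]])
  })
  if (region == "center") {
    d <- dim(maps[[1]]$absorbance)
    cm <- center_region_mask(d[1L], d[2L], min(config$center_size, d[1L], d[2L]))
    masks <- purrr::map(masks, function(mk) mask_intersect(mk, cm))
    return(pool_pixels(maps, masks[names(maps)]))
  }
  # pacmap arm: embed the QC-passing pixels, then reject kNN outliers
  pool0 <- pool_pixels(maps, masks[names(maps)])
  emb <- embed_pixels(pool0, band = config$embed_band,
                      seed = sub_seed(config$seed, "embed"))
  d <- dim(maps[[1]]$absorbance)
  om <- outlier_mask(emb, config$outlier_percentile, d[1L], d[2L])
  keep <- om$emb$accepted
  out <- pool0[keep, ]
  attr(out, "axis") <- pool_axis(pool0)
  attr(out, "embedding") <- om$emb
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> QC -> preprocess -> pool (center and/or embedding region) ->
#' train -> predict -> evaluate, as one seeded, reproducible run. Samples
#' retaining zero QC-passing pixels are excluded from classification and
#' counted in the manifest.
#'
#' @param config a [run_config()].
#' @param maps,meta optionally, an existing cohort (named list of maps and
#'   its metadata tibble) instead of simulating one.
#' @return A list of class `radsig_run`: `meta`, `qc_summary`,
#'   `dropped_samples`, per-region lists with `models`, `predictions`,
#'   `reports`, a `comparison` tibble (family x region x pixel/sample
#'   accuracy), and `manifest` (parameter echo + artifact hashes when
#'   `output_dir` is set).
#' @export
run_pipeline <- function(config = run_config(), maps = NULL, meta = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(maps)) {
    cohort <- generate_cohort(config$synth)
    maps <- cohort$maps
    meta <- cohort$meta
  }
  qc <- qc_cohort(maps, config$qc)
  pre <- purrr::map(maps, preprocess_map, params = config$preprocess)
  valid <- purrr::map(pre, function(m) {
    pixel_mask(attr(m, "valid_pixels"), "valid")
  })
  dropped <- qc$summary$sample_id[qc$summary$n_retained == 0L]
  keep_ids <- setdiff(names(maps), dropped)
  pre_keep <- pre[keep_ids]

  regions <- switch(config$region_mode,
                    both = c("center", "pacmap"),
                    config$region_mode)
  region_results <- purrr::map(regions, function(region) {
    pool <- pool_for_region(pre_keep, meta, qc$masks[keep_ids], valid[keep_ids],
                            region, config)
    parts <- split_pool(pool)
    ft_train <- build_features(parts$train, config$features,
                               label = config$label_mode)
    models <- purrr::map(config$families, function(fam) {
      spec <- model_spec(fam, epochs = config$epochs,
                         batch_size = config$batch_size,
                         seed = sub_seed(config$seed, paste0("model:", fam, ":", region)))
      if (config$label_mode == "dose") {
        train_model_multiclass(spec, ft_train$x, ft_train$y)
      } else {
        train_model(spec, ft_train$x, ft_train$y,
                    sample_id = ft_train$pool_info$sample_id)
      }
    })
    names(models) <- config$families
    predictions <- purrr::map(models, function(m) {
      if (config$label_mode == "dose") {
        predict_pool_multiclass(m, parts$test, config$features)
      } else {
        predict_pool(m, parts$test, config$features)
      }
    })
    reports <- if (config$label_mode == "binary") {
      purrr::map(predictions, stratified_report, n_perm = config$n_perm,
                 seed = sub_seed(config$seed, "perm"))
    } else {
      purrr::map(predictions, multiclass_report)
    }
    list(pool_sizes = c(train = nrow(parts$train), test = nrow(parts$test)),
         models = models, predictions = predictions, reports = reports)
  })
  names(region_results) <- regions

  comparison <- purrr::imap(region_results, function(res, region) {
    purrr::imap(res$reports, function(rep, fam) {
      if (inherits(rep, "radsig_eval")) {
        tibble::tibble(region = region, family = fam,
                       pixel_accuracy = rep$overall$pixel_accuracy,
                       sample_accuracy = rep$overall$sample_accuracy,
                       balanced_accuracy = rep$overall$balanced_accuracy,
                       auc = rep$overall$auc)
      } else {
        tibble::tibble(region = region, family = fam,
                       pixel_accuracy = rep$pixel_accuracy,
                       sample_accuracy = rep$sample_accuracy,
                       balanced_accuracy = NA_real_, auc = NA_real_)
      }
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  run <- structure(list(
    meta = meta, qc_summary = qc$summary, dropped_samples = dropped,
    regions = region_results, comparison = comparison,
    config = config
  ), class = "radsig_run")
  if (!is.null(config$output_dir)) {
    run$manifest <- write_run_artifacts(run, config$output_dir)
  }
  run
}

#' @method print radsig_run
#' @export
print.radsig_run <- function(x, ...) {
  cat(sprintf("<radsig_run> %d samples (%d dropped by QC), regions: %s\n",
              nrow(x$meta), length(x$dropped_samples),
              paste(names(x$regions), collapse = ", ")))
  print(x$comparison)
  invisible(x)
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(run$qc_summary, file.path(dir, "qc_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(run$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  preds <- purrr::imap(run$regions, function(res, region) {
    purrr::imap(res$predictions, function(p, fam) {
      if (!inherits(p, "radsig_prediction")) return(NULL)
      dplyr::bind_cols(tibble::tibble(region = region, family = fam), p$samples)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  utils::write.csv(preds, file.path(dir, "preds.csv"), row.names = FALSE)
  report <- purrr::map(run$regions, function(res) {
    purrr::map(res$reports, function(r) {
      if (inherits(r, "radsig_eval")) {
        list(overall = as.list(r$overall), by_dose = r$by_dose,
             by_day = r$by_day, permutation_p = r$permutation_p)
      } else {
        r
      }
    })
  })
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("cohort.csv", "qc_summary.csv", "comparison.csv", "preds.csv",
             "report.json")
  manifest <- list(
    seed = run$config$seed,
    region_mode = run$config$region_mode,
    families = run$config$families,
    n_samples = nrow(run$meta),
    dropped_samples = run$dropped_samples,
    file_md5 = as.list(tools::md5sum(file.path(dir, files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

## ---- optional multi-class dose mode ----

# One-vs-rest wrapper reusing the binary machinery; the flat dose-response
# of the signature makes this mode weak by construction, and it is reported
# as such rather than tuned.
train_model_multiclass <- function(spec, x, y) {
  lev <- levels(y)
  fits <- purrr::map(lev, function(lv) {
    train_model(spec, x, as.integer(y == lv))
  })
  structure(list(spec = spec, levels = lev, fits = fits,
                 wavenumber = as.numeric(colnames(x))),
            class = "radsig_multiclass_model")
}

predict_pool_multiclass <- function(model, pool, fspec = feature_spec()) {
  ft <- build_features(pool, fspec, label = "dose")
  probs <- do.call(cbind, purrr::map(model$fits, predict, newdata = ft$x))
  colnames(probs) <- model$levels
  pick <- model$levels[max.col(probs, ties.method = "first")]
  pixels <- dplyr::bind_cols(
    dplyr::select(pool, dplyr::any_of(c("sample_id", "row", "col", "dose_gy", "day"))),
    tibble::tibble(pred_dose = pick)
  )
  samples <- pixels |>
    dplyr::group_by(.data$sample_id, .data$dose_gy, .data$day) |>
    dplyr::summarise(
      pred_dose = names(which.max(table(.data$pred_dose))),
      n_pixels = dplyr::n(), .groups = "drop"
    )
  list(pixels = pixels, samples = samples,
       pixel_accuracy = mean(pixels$pred_dose == as.character(pixels$dose_gy)),
       sample_accuracy = mean(samples$pred_dose == as.character(samples$dose_gy)))
}

multiclass_report <- function(pred) {
  list(pixel_accuracy = pred$pixel_accuracy,
       sample_accuracy = pred$sample_accuracy,
       confusion = table(truth = as.character(pred$samples$dose_gy),
                         predicted = pred$samples$pred_dose))
}
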