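test_that("balanced accuracy is the mean of sensitivity and specificity", {
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_identical(balanced_accuracy(labels, labels), 1)
  expect_identical(balanced_accuracy(labels, rep(1, 8)), 0.5)
  # sens 0.9, spec 0.42 -> 0.66 on a constructed table
  labs <- c(rep(1, 10), rep(0, 50))
  preds <- c(rep(1, 9), 0, rep(1, 29), rep(0, 21))
  expect_equal(balanced_accuracy(labs, preds), (0.9 + 0.42) / 2)
  expect_error(balanced_accuracy(rep(1, 4), rep(1, 4)), "single class")
})

test_that("ROC and AUC behave canonically and match the rank statistic", {
  labels <- c(rep(0, 5), rep(1, 5))
  perfect <- seq(0.1, 1, by = 0.1)
  expect_identical(roc_and_auc(perfect, labels)$auc, 1)
  # sign reversal flips the area
  set.seed(31)
  for (i in 1:10) {
    sc <- rnorm(40)
    la <- rbinom(40, 1, 0.5)
    if (length(unique(la)) < 2) next
    r <- roc_and_auc(sc, la)
    expect_equal(roc_and_auc(-sc, la)$auc, 1 - r$auc, tolerance = 1e-12)
    # AUC = P(random positive outscores random negative), tie-corrected
    pos <- sc[la == 1]; neg <- sc[la == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(cmp), tolerance = 1e-12)
    # monotone curve
    expect_true(all(diff(r$roc$tpr) >= 0))
    expect_true(all(diff(r$roc$fpr) >= 0))
  }
})

test_that("our ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- rnorm(60)
  la <- rbinom(60, 1, 0.4)
  ours <- roc_and_auc(sc, la)$auc
  theirs <- suppressMessages(as.numeric(pROC::auc(la, sc)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("specificity at fixed sensitivity equals the brute-force cutoff search", {
  brute <- function(scores, labels, s0) {
    cuts <- sort(unique(scores), decreasing = TRUE)
    best <- NA
    for (ct in c(Inf, cuts)) {
      pred <- as.integer(scores >= ct)
      sens <- mean(pred[labels == 1] == 1)
      if (sens >= s0) { best <- mean(pred[labels == 0] == 0); break }
    }
    best
  }
  set.seed(23)
  for (i in 1:20) {
    sc <- round(runif(10), 2)   # duplicates likely
    la <- rbinom(10, 1, 0.5)
    if (sum(la) == 0 || sum(la) == 10) next
    expect_equal(specificity_at_sensitivity(sc, la, 0.9), brute(sc, la, 0.9))
  }
  # perfect separation: specificity 1 at any pin
  la <- c(rep(0, 5), rep(1, 5))
  expect_identical(specificity_at_sensitivity(seq(0.1, 1, 0.1), la, 0.9), 1)
  # all-tied scores: everything must be called positive -> specificity 0
  expect_identical(specificity_at_sensitivity(rep(0.5, 10), la, 0.9), 0)
  expect_error(specificity_at_sensitivity(runif(5), rep(0, 5), 0.9),
               "unreachable")
})

test_that("permutation p-values use the add-one estimator and stay in (0, 1]", {
  # perfectly separated data: no permutation ties the observed AUC
  la <- c(rep(0, 10), rep(1, 10))
  sc <- c(seq(0.01, 0.10, 0.01), seq(0.9, 0.99, 0.01))
  p <- permutation_pvalue(function(l, s) roc_and_auc(s, l)$auc, la, sc,
                          n_perm = 999L, seed = 4L)
  expect_equal(p, 1 / 1000)
  # null data: p is well inside the unit interval and roughly uniform
  set.seed(77)
  ps <- replicate(40, {
    la2 <- rbinom(20, 1, 0.5)
    if (length(unique(la2)) < 2) return(NA_real_)
    permutation_pvalue(function(l, s) roc_and_auc(s, l)$auc, la2, rnorm(20),
                       n_perm = 199L, seed = sample.int(1e6, 1))
  })
  ps <- ps[!is.na(ps)]
  expect_true(all(ps > 0 & ps <= 1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_error(permutation_pvalue(balanced_accuracy, la, sc, n_perm = 10L),
               "at least 100")
})

# a hand-built prediction object with known strata
fake_prediction <- function() {
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    n_pixels = 10L, n_positive = c(9, 8, 9, 2, 1, 2, 9, 8, 2, 1, 8, 2),
    vote_fraction = n_positive / 10,
    label = as.integer(vote_fraction > 0.5),
    mouse_id = sprintf("m%02d", 1:12),
    dose_gy = c(1, 1, 2, 0, 0, 0, 1, 2, 0, 0, 2, 0),
    day = rep(c(5L, 14L), each = 6),
    exposed = as.integer(dose_gy > 0)
  )
  pixels <- tibble::tibble(
    sample_id = rep(samples$sample_id, each = 10),
    exposed = rep(samples$exposed, each = 10),
    pixel_label = unlist(lapply(samples$n_positive, function(k) {
      c(rep(1L, k), rep(0L, 10 - k))
    }))
  )
  structure(list(pixels = pixels, samples = samples, family = "test"),
            class = "radsig_prediction")
}

test_that("stratified metrics reduce to pooled metrics for a single stratum", {
  pred <- fake_prediction()
  pred$samples <- pred$samples[pred$samples$day == 5L, ]
  pred$pixels <- pred$pixels[pred$pixels$sample_id %in% pred$samples$sample_id, ]
  rep1 <- stratified_report(pred)
  expect_identical(nrow(rep1$by_day), 1L)
  expect_equal(rep1$by_day$balanced_accuracy, rep1$overall$balanced_accuracy)
  expect_equal(rep1$by_day$auc, rep1$overall$auc)
})

test_that("dose strata share controls and partition the exposed samples", {
  pred <- fake_prediction()
  rep1 <- stratified_report(pred)
  # each dose stratum: that dose's exposed + all 6 controls
  expect_identical(rep1$by_dose$n_control, rep(6L, 2))
  expect_identical(sum(rep1$by_dose$n_exposed),
                   sum(pred$samples$exposed == 1))
  # overall block carries both accuracy levels
  expect_true(all(c("pixel_accuracy", "sample_accuracy", "balanced_accuracy",
                    "auc", "spec_at_sens_0.9") %in% names(rep1$overall)))
  # tidy() exposes one row per stratum
  td <- tidy(rep1)
  expect_identical(td$stratum[1], "overall")
  expect_true(all(c("dose:1", "dose:2", "day:5", "day:14") %in% td$stratum))
})

test_that("the report's permutation test flags real signal", {
  pred <- fake_prediction()
  rep1 <- stratified_report(pred, n_perm = 199L, seed = 8L)
  expect_lt(rep1$permutation_p, 0.05)
  gl <- glance(rep1)
  expect_identical(gl$permutation_p, rep1$permutation_p)
})
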