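test_that("noise-free spectrum equals the analytic band sum plus baseline", {
  cfg <- clean_config(baseline_params = list(coefs = c(0, 0, 0), scatter = 0))
  ax <- synth_axis(cfg)
  s <- generate_spectrum(cfg, dose = 0, day = 14)
  expect_equal(s, oracle_band_sum(ax), tolerance = 1e-12)
  # amide I (1648) dominates e.g. the tyrosine band (1518)
  at <- function(w) s[which.min(abs(ax - w))]
  expect_gt(at(1648), at(1518))
  expect_gt(at(1648), at(2922))
})

test_that("exposure moves the O-P-O second-derivative minimum 1236 -> 1240", {
  cfg <- clean_config(baseline_params = list(coefs = c(0, 0, 0), scatter = 0))
  ax <- synth_axis(cfg)
  d2_ctl <- second_derivative(generate_spectrum(cfg, 0, 14), ax)
  d2_trt <- second_derivative(generate_spectrum(cfg, 1, 14), ax)
  win <- which(ax >= 1230 & ax <= 1245)
  min_ctl <- ax[win[which.min(d2_ctl[win])]]
  min_trt <- ax[win[which.min(d2_trt[win])]]
  spacing <- abs(diff(ax))[1]
  expect_lt(abs(min_ctl - 1236), spacing)
  expect_lt(abs(min_trt - 1240), spacing)
})

test_that("flat dose-response makes all positive doses identical; linear does not", {
  cfg <- clean_config(doses = c(0, 0.1, 2))
  s_low <- generate_spectrum(cfg, 0.1, 14)
  s_high <- generate_spectrum(cfg, 2, 14)
  expect_identical(s_low, s_high)
  cfg_lin <- clean_config(doses = c(0, 0.1, 2), dose_response = "linear")
  expect_false(identical(generate_spectrum(cfg_lin, 0.1, 14),
                         generate_spectrum(cfg_lin, 2, 14)))
})

test_that("day-effect profile modulates the injected effect, peaking at day 14", {
  cfg <- clean_config(days = c(5L, 14L, 90L))
  ax <- synth_axis(cfg)
  ctl <- generate_spectrum(cfg, 0, 14)
  eff_at <- function(day) {
    # injected perturbation magnitude at the beta-sheet band (1626)
    trt <- generate_spectrum(cfg, 1, day)
    i <- which.min(abs(ax - 1626))
    abs(trt[i] - ctl[i])
  }
  expect_gt(eff_at(14), eff_at(5))
  expect_gt(eff_at(14), eff_at(90))
  expect_gt(eff_at(5), eff_at(90))
})

test_that("generated maps have the native pixel count and are seed-reproducible", {
  cfg <- synth_config(n_rows = 128L, n_cols = 128L, n_points = 64L,
                      doses = c(0, 1), days = 14L, seed = 5L)
  m <- generate_map(cfg, 0, 14, "M001", seed = 9L)
  d <- dim(m$absorbance)
  expect_identical(d[1] * d[2], 16384L)
  m2 <- generate_map(cfg, 0, 14, "M001", seed = 9L)
  expect_identical(m$absorbance, m2$absorbance)
  m3 <- generate_map(cfg, 0, 14, "M001", seed = 10L)
  expect_false(identical(m$absorbance, m3$absorbance))
})

test_that("dead pixels appear at the configured rate and not when rate is 0", {
  cfg0 <- tiny_config(dead_pixel_rate = 0, n_rows = 12L, n_cols = 12L,
                      n_points = 256L)
  m0 <- generate_map(cfg0, 0, 14, "M001", seed = 3L)
  totals0 <- apply(m0$absorbance, c(1, 2), sum)
  expect_true(all(totals0 > 0.1 * median(totals0)))
  cfg1 <- tiny_config(dead_pixel_rate = 0.2, n_rows = 12L, n_cols = 12L,
                      n_points = 256L)
  m1 <- generate_map(cfg1, 0, 14, "M001", seed = 3L)
  totals1 <- apply(m1$absorbance, c(1, 2), sum)
  expect_gt(sum(totals1 < 0.1 * median(totals1)), 0)
})

test_that("cohort design: one dose per mouse, sample-level split, full grid", {
  cfg <- synth_config(n_mice_per_group = 3L, doses = c(0, 0.5, 2), days = c(5L, 14L),
                      n_rows = 4L, n_cols = 4L, n_points = 128L, seed = 11L)
  coh <- generate_cohort(cfg)
  expect_identical(length(coh$maps), 3L * 3L * 2L)
  per_mouse <- dplyr::distinct(coh$meta, mouse_id, dose_gy)
  expect_identical(nrow(per_mouse), 9L)  # one dose per mouse
  split_by_mouse <- dplyr::distinct(coh$meta, mouse_id, split)
  expect_identical(nrow(split_by_mouse), 9L)  # one split per mouse
  expect_setequal(unique(coh$meta$split), c("train", "test"))
  # every dose group contains both splits
  tab <- table(coh$meta$dose_gy, coh$meta$split)
  expect_true(all(tab > 0))
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- synth_config(n_mice_per_group = 1L, doses = c(0, 1), days = 14L,
                      n_rows = 4L, n_cols = 4L, n_points = 128L, seed = 21L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$meta, c2$meta)
  expect_identical(
    serialize(c1$maps, NULL),
    serialize(c2$maps, NULL)
  )
})

test_that("configuration errors are caught", {
  expect_error(synth_config(doses = numeric(0)), "non-empty")
  expect_error(synth_config(dead_pixel_rate = 1), "\\[0, 1\\)")
  expect_error(synth_config(axis_start = 900, axis_end = 3900), "exceed")
  bt <- synth_band_table()
  bt$position[1] <- 5000
  expect_error(synth_config(band_table = bt), "within the spectral axis")
  cfg <- tiny_config()
  expect_error(generate_spectrum(cfg, dose = 7, day = 14), "dose")
  expect_error(generate_spectrum(cfg, dose = 0, day = 3), "day")
})
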