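test_that("SG second derivative is exact on polynomials up to the fit order", {
  ax <- seq(2000, 1000, length.out = 501)
  h <- 2  # edge width for the default window of 5
  inner <- (h + 1):(length(ax) - h)
  # quadratic: second derivative 2a
  d2 <- second_derivative(3 * ax^2 - 2 * ax + 7, ax)
  expect_equal(d2[inner], rep(6, length(inner)), tolerance = 1e-6)
  # cubic: second derivative 6a x + 2b
  d2c <- second_derivative(0.5 * ax^3 + 2 * ax^2, ax)
  expect_equal(d2c[inner], 3 * ax[inner] + 4, tolerance = 1e-4)
  # straight line: zero
  d2l <- second_derivative(5 - 0.1 * ax, ax)
  expect_equal(d2l[inner], rep(0, length(inner)), tolerance = 1e-8)
  # edges are flagged, not extrapolated
  expect_true(all(is.na(d2[c(1:h, (length(ax) - h + 1):length(ax))])))
})

test_that("an absorbance maximum maps to a derivative minimum at the same point", {
  cfg <- clean_config(baseline_params = list(coefs = c(0, 0, 0), scatter = 0))
  ax <- synth_axis(cfg)
  bt <- synth_band_table()
  spacing <- abs(diff(ax))[1]
  # single Gaussian: analytic check at 1648
  g <- exp(-(ax - 1648)^2 / (2 * 7^2))
  d2g <- second_derivative(g, ax)
  expect_equal(ax[which.min(d2g)], ax[which.max(g)])
  # full noise-free band mixture: at every reference band the derivative
  # minimum sits within one axis step of the local absorbance maximum
  s <- generate_spectrum(cfg, 0, 14)
  d2 <- second_derivative(s, ax)
  pm <- peak_minima(d2, ax, bt, search_halfwidth = 10)
  expect_true(all(pm$found))
  expect_true(all(abs(pm$found_cm1 - pm$nominal_cm1) <= 2 * spacing + 1e-9))
})

test_that("derivative scales with physical spacing, not index units", {
  ax1 <- seq(2000, 1000, length.out = 501)   # 2 cm^-1 spacing
  ax2 <- seq(2000, 1000, length.out = 251)   # 4 cm^-1 spacing
  f <- function(x) 2 * x^2
  d1 <- second_derivative(f(ax1), ax1)
  d2 <- second_derivative(f(ax2), ax2)
  expect_equal(d1[100], 4, tolerance = 1e-6)
  expect_equal(d2[100], 4, tolerance = 1e-6)
  # non-uniform axis is rejected
  expect_error(second_derivative(f(ax1), ax1^1.01), "uniform")
})

test_that("group means and difference spectra follow their definitions", {
  pool <- clean_pool()
  gm <- group_mean_spectra(pool, "exposed")
  expect_identical(nrow(gm), 2L)
  # brute-force column mean oracle
  rows <- pool$exposed == 0
  expect_equal(gm$spectrum[gm$exposed == 0, ],
               colMeans(pool$spectrum[rows, , drop = FALSE]))
  # identical pixels: mean equals any member
  one <- pool[rep(1, 5), ]
  attr(one, "axis") <- pool_axis(pool)
  gm1 <- group_mean_spectra(one, "exposed")
  expect_equal(gm1$spectrum[1, ], as.vector(pool$spectrum[1, ]))
  # {v, -v} averages to zero; negate twice restores
  v <- rnorm(10)
  expect_equal(difference_spectrum(v, v), rep(0, 10))
  expect_equal(difference_spectrum(difference_spectrum(v, rep(0, 10), negate = TRUE),
                                   rep(0, 10), negate = TRUE), v)
  expect_error(difference_spectrum(v, v[-1]), "share one axis")
})

test_that("peak_minima resolves overlapping amide-I sub-bands and flags flats", {
  ax <- seq(1800, 1500, by = -0.5)
  two <- 1.3 * exp(-(ax - 1648)^2 / (2 * 7^2)) + 0.75 * exp(-(ax - 1626)^2 / (2 * 7^2))
  d2 <- second_derivative(two, ax)
  recs <- tibble::tibble(peak_number = 1:2, position = c(1648, 1626))
  pm <- peak_minima(d2, ax, recs, search_halfwidth = 8)
  expect_true(all(pm$found))
  expect_lt(abs(pm$found_cm1[1] - 1648), 2)
  expect_lt(abs(pm$found_cm1[2] - 1626), 2)
  expect_true(all(pm$peak_to_peak > 0))
  # flat spectrum: nothing found, not fatal
  flat <- peak_minima(rep(0, length(ax)), ax, recs)
  expect_true(all(!flat$found))
})

test_that("second-derivative intensity statistics are monotone in amplitude", {
  ax <- seq(1800, 1400, by = -1)
  amps <- c(0.5, 1, 2)
  stats <- sapply(amps, function(a) {
    d2 <- second_derivative(a * exp(-(ax - 1648)^2 / (2 * 9^2)), ax)
    pm <- peak_minima(d2, ax, tibble::tibble(peak_number = 1L, position = 1648))
    c(-pm$intensity, pm$peak_to_peak)
  })
  expect_true(all(diff(stats[1, ]) > 0))
  expect_true(all(diff(stats[2, ]) > 0))
})

test_that("peak_shift recovers the exposure-induced band shifts", {
  pool <- clean_pool()
  ax <- pool_axis(pool)
  gm <- group_mean_spectra(pool, "exposed")
  d2c <- second_derivative(gm$spectrum[gm$exposed == 0, ], ax)
  d2t <- second_derivative(gm$spectrum[gm$exposed == 1, ], ax)
  spacing <- abs(diff(ax))[1]
  expect_lt(abs(peak_shift(d2c, d2t, ax, 1236) - 4), spacing + 1e-9)
  expect_lt(abs(peak_shift(d2c, d2t, ax, 1735) - 8), spacing + 1e-9)
  expect_identical(peak_shift(d2c, d2c, ax, 1236), 0)
  expect_error(peak_shift(rep(0, length(ax)), d2t, ax, 1236), "no local minimum")
})

test_that("noise-free difference spectrum reproduces the injected effect sizes", {
  pool <- clean_pool()
  bd <- band_difference_table(pool)
  bt <- synth_band_table()
  # recovered = -(treated - control) for "up" bands, +(treated - control)
  # for "down" bands; reference band (1553) carries no direct injection
  recovered <- -bd$delta_intensity_1e4 * ifelse(bt$direction == "up", 1, -1)
  check <- bt$position != 1553
  expect_true(all(abs(recovered[check] - bt$delta_intensity[check]) /
                    bt$delta_intensity[check] < 0.25))
  # the two headline amide-I effects at their printed sizes
  expect_equal(recovered[bt$position == 1648], 1.1, tolerance = 0.25)
  expect_equal(recovered[bt$position == 1626], 1.5, tolerance = 0.25)
})

test_that("derivative parameter validation enforces window > order >= deriv", {
  expect_error(deriv_params(window_length = 3L, polyorder = 5L), "window_length")
  expect_error(deriv_params(window_length = 5L, polyorder = 1L), "polyorder")
  expect_s3_class(deriv_params(7L, 3L), "deriv_params")
})
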