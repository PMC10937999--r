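test_that("clip_range restricts to the closed window and is idempotent", {
  cfg <- tiny_config(n_rows = 4L, n_cols = 4L, n_points = 512L)
  m <- generate_map(cfg, 0, 14, "M001", seed = 1L)
  p <- preprocess_params()
  cl <- clip_range(m, p)
  expect_lte(max(cl$axis), 3600)
  expect_gte(min(cl$axis), 900)
  cl2 <- clip_range(cl, p)
  expect_identical(cl2$absorbance, cl$absorbance)
  # clipping to the full range is the identity
  full <- clip_range(m, preprocess_params(clip_window = c(900, 3900),
                                          baseline_anchors = c(3900, 900)))
  expect_identical(full$absorbance, m$absorbance)
})

test_that("fill_dead_pixels replaces dead pixels by their neighborhood mean", {
  ax <- seq(3600, 900, length.out = 64)
  base <- rep(1, 64)
  m <- constant_map(base, ax, 6, 6)
  m$absorbance[3, 3, ] <- 0.001     # dead pixel in the interior
  filled <- fill_dead_pixels(m, preprocess_params())
  expect_equal(filled$absorbance[3, 3, ], base, tolerance = 1e-12)
  expect_true(attr(filled, "dead_pixels")[3, 3])
  expect_identical(sum(attr(filled, "dead_pixels")), 1L)
  # untouched elsewhere
  expect_identical(filled$absorbance[1, 1, ], m$absorbance[1, 1, ])
  # no dead pixels -> identity
  m2 <- constant_map(base, ax, 4, 4)
  expect_identical(fill_dead_pixels(m2)$absorbance, m2$absorbance)
  # all dead -> error
  m3 <- constant_map(rep(0, 64), ax, 4, 4)
  m3$absorbance[] <- 0
  expect_error(fill_dead_pixels(m3), "unusable")
})

test_that("corner dead pixel uses the truncated in-bounds neighborhood", {
  ax <- seq(3600, 900, length.out = 32)
  n <- 5
  set.seed(99)
  cube <- array(runif(n * n * 32, 0.5, 1.5), dim = c(n, n, 32))
  cube[1, 1, ] <- 0                    # dead at a corner
  m <- hyperspec_map(cube, ax, list(sample_id = "corner"))
  filled <- fill_dead_pixels(m, preprocess_params())
  # brute-force oracle: mean over in-bounds non-dead 5x5 window at (1,1)
  nb <- expand.grid(r = 1:3, c = 1:3)
  nb <- nb[!(nb$r == 1 & nb$c == 1), ]
  oracle <- colMeans(t(sapply(seq_len(nrow(nb)), function(i) cube[nb$r[i], nb$c[i], ])))
  expect_equal(filled$absorbance[1, 1, ], oracle, tolerance = 1e-12)
})

test_that("median_denoise matches the brute-force sorted median on random maps", {
  set.seed(7)
  for (trial in 1:20) {
    n <- 9
    cube <- array(rnorm(n * n * 3), dim = c(n, n, 3))
    ax <- seq(2000, 1000, length.out = 3)
    m <- hyperspec_map(cube, ax, list(sample_id = "rnd"))
    den <- median_denoise(m, preprocess_params(median_kernel = 5L))
    r <- sample(n, 1); c <- sample(n, 1); ch <- sample(3, 1)
    rr <- max(1, r - 2):min(n, r + 2)
    cc <- max(1, c - 2):min(n, c + 2)
    expect_equal(den$absorbance[r, c, ch],
                 median(cube[rr, cc, ch]), tolerance = 1e-12)
  }
})

test_that("median_denoise leaves constant maps alone and removes spikes", {
  ax <- seq(2000, 1000, length.out = 8)
  m <- constant_map(rep(2, 8), ax, 7, 7)
  expect_equal(median_denoise(m)$absorbance, m$absorbance, tolerance = 1e-12)
  m$absorbance[4, 4, ] <- m$absorbance[4, 4, ] + 10
  den <- median_denoise(m)
  expect_equal(den$absorbance[4, 4, ], rep(2, 8), tolerance = 1e-12)
})

test_that("rubber-band correction annihilates straight-line spectra", {
  ax <- seq(3600, 900, length.out = 1024)
  line <- 0.3 + 1e-4 * ax
  out <- rubberband_baseline(line, ax)
  expect_lt(max(abs(out$corrected)), 1e-9)
})

test_that("rubber-band correction recovers a Gaussian peak on a linear baseline", {
  ax <- seq(3600, 900, length.out = 1024)
  peak <- exp(-(ax - 1650)^2 / (2 * 12^2))
  s <- 0.2 + 5e-5 * ax + peak
  out <- rubberband_baseline(s, ax)
  i <- which.min(abs(ax - 1650))
  expect_equal(out$corrected[i], 1, tolerance = 0.01)
  # baseline never exceeds the spectrum at hull support; corrected >= at
  # the anchors' snapped minima (exact zeros there)
  p <- preprocess_params()
  for (a in p$baseline_anchors) {
    w <- which(abs(ax - a) <= p$anchor_halfwidth)
    expect_lt(min(abs(out$corrected[w])), 1e-12)
  }
})

test_that("rubber-band baseline is the identity on convex spectra", {
  ax <- seq(3600, 900, length.out = 512)
  convex <- 1e-7 * (ax - 2000)^2 + 0.1
  out <- rubberband_baseline(convex, ax)
  expect_lt(max(abs(out$corrected)), 1e-9)
})

test_that("amide-II normalization scales the window maximum to one", {
  ax <- seq(3600, 900, length.out = 1024)
  s <- 0.5 * exp(-(ax - 1553)^2 / (2 * 9^2)) + 0.9 * exp(-(ax - 1648)^2 / (2 * 9^2))
  ns <- normalize_amide2(s, ax)
  sb <- slice_band(ns, ax, 1480, 1590)
  expect_equal(max(sb$values), 1, tolerance = 1e-12)
  # value at 1648 scales by 1/0.5 (up to band overlap)
  i <- which.min(abs(ax - 1648))
  expect_equal(ns[i], s[i] / max(slice_band(s, ax, 1480, 1590)$values))
  # already normalized -> identity
  expect_equal(normalize_amide2(ns, ax), ns, tolerance = 1e-12)
  # non-positive window -> degenerate pixel error
  expect_error(normalize_amide2(-s, ax), class = "radsig_degenerate_pixel")
})

test_that("preprocess_map composes the five stages and is nearly idempotent", {
  # co2_amplitude = 0: per-pixel CO2 variability is the one spatial field a
  # second median-filter pass would keep reshaping
  cfg <- clean_config(n_rows = 6L, n_cols = 6L, n_points = 1024L,
                      co2_amplitude = 0)
  m <- generate_map(cfg, 0, 14, "M001", seed = 5L)
  pp <- preprocess_map(m)
  expect_lte(max(pp$axis), 3600)
  expect_gte(min(pp$axis), 900)
  # every pixel's amide II max is exactly 1
  d <- dim(pp$absorbance)
  flat <- matrix(pp$absorbance, d[1] * d[2], d[3])
  sb <- slice_band(flat, pp$axis, 1480, 1590)
  expect_equal(unname(apply(sb$values, 1, max)), rep(1, d[1] * d[2]),
               tolerance = 1e-9)
  # the generator's smooth baseline is removed: off-band regions ~ 0
  quiet <- slice_band(flat, pp$axis, 1950, 2250)
  expect_lt(max(abs(quiet$values)), 0.02)
  # approximate idempotence (absolute, on the normalized scale)
  pp2 <- preprocess_map(pp)
  expect_lt(max(abs(pp2$absorbance - pp$absorbance)), 1e-6)
})

test_that("parameter validation rejects invalid kernels and anchors", {
  expect_error(preprocess_params(fill_kernel = 4L), "fill_kernel")
  expect_error(preprocess_params(median_kernel = 1L), "median_kernel")
  expect_error(preprocess_params(baseline_anchors = c(3700, 900)),
               "inside `clip_window`")
})
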