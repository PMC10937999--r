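# constructs a pixel spectrum with controllable amide peak, noise amplitude
# in the quiet range, and CO2 amplitude
make_pixel <- function(axis, amide = 1, noise_amp = 0, co2 = 0) {
  s <- amide * exp(-(axis - 1648)^2 / (2 * 9^2))
  nw <- which(axis >= 1800 & axis <= 2300)
  s[nw] <- s[nw] + noise_amp * rep_len(c(1, -1), length(nw))
  s + co2 * exp(-(axis - 2350)^2 / (2 * 15^2))
}

test_that("amide, CO2 and noise signals follow their definitions", {
  ax <- seq(3900, 900, by = -1)
  p <- qc_params()
  s <- make_pixel(ax, amide = 1)
  expect_equal(amide_signal(s, ax, p), 1, tolerance = 1e-6)
  expect_equal(amide_signal(numeric(length(ax)), ax, p), 0)
  # window excludes a larger band outside it
  s2 <- 0.8 * exp(-(ax - 1648)^2 / 200) + 1.2 * exp(-(ax - 1553)^2 / 200)
  expect_equal(amide_signal(s2, ax, p), 0.8, tolerance = 1e-3)
  # noise level is the window sd: direct computation oracle
  s3 <- make_pixel(ax, noise_amp = 0.004)
  nw <- which(ax >= 1800 & ax <= 2300)
  expect_equal(noise_level(s3, ax, p), sd(s3[nw]))
  # shift invariance
  expect_equal(noise_level(s3 + 5, ax, p), noise_level(s3, ax, p))
  expect_equal(noise_level(rep(1, length(ax)), ax, p), 0)
})

test_that("qc_mask accepts and rejects per the SNR and CO2 ratio rules", {
  ax <- seq(3900, 900, by = -1)
  p <- qc_params()
  good <- make_pixel(ax, amide = 1, noise_amp = 0.004, co2 = 0.05)
  noisy <- make_pixel(ax, amide = 1, noise_amp = 0.006, co2 = 0.05)
  co2y <- make_pixel(ax, amide = 1, noise_amp = 0.004, co2 = 0.10)
  dead <- numeric(length(ax))
  cube <- array(0, dim = c(2, 2, length(ax)))
  cube[1, 1, ] <- good; cube[2, 1, ] <- noisy
  cube[1, 2, ] <- co2y; cube[2, 2, ] <- dead
  m <- hyperspec_map(cube, ax, list(sample_id = "qc"))
  mask <- qc_mask(m, p)
  # arithmetic oracle: snr = max/sd, ratio = max/max
  nw <- which(ax >= 1800 & ax <= 2300)
  cw <- which(ax >= 2300 & ax <= 2400)
  aw <- which(ax >= 1600 & ax <= 1700)
  oracle <- function(s) {
    max(s[aw]) / sd(s[nw]) >= 200 && max(s[aw]) / max(s[cw]) >= 15
  }
  expect_identical(mask$accepted[1, 1], oracle(good))
  expect_true(mask$accepted[1, 1])
  expect_identical(mask$accepted[2, 1], oracle(noisy))
  expect_false(mask$accepted[2, 1])    # SNR ~ 167 < 200
  expect_false(mask$accepted[1, 2])    # amide/CO2 = 10 < 15
  expect_false(mask$accepted[2, 2])    # dead pixel
})

test_that("degenerate denominators pass rather than reject", {
  ax <- seq(3900, 900, by = -1)
  clean <- make_pixel(ax, amide = 1, noise_amp = 0, co2 = 0)
  cube <- array(rep(clean, each = 1), dim = c(1, 1, length(ax)))
  m <- hyperspec_map(cube, ax, list(sample_id = "clean"))
  expect_true(qc_mask(m)$accepted[1, 1])
})

test_that("raising the SNR threshold never adds accepted pixels", {
  cfg <- tiny_config(n_rows = 8L, n_cols = 8L, n_points = 1024L)
  m <- generate_map(cfg, 0, 14, "M001", seed = 4L)
  loose <- qc_mask(m, qc_params(snr_threshold = 100))
  strict <- qc_mask(m, qc_params(snr_threshold = 300))
  expect_true(all(loose$accepted | !strict$accepted))  # strict subset of loose
})

test_that("rank_and_cap keeps the quietest pixels up to the cap", {
  ax <- seq(3900, 900, by = -2)
  n <- 6
  cube <- array(0, dim = c(n, n, length(ax)))
  noise_amp <- matrix(seq(0.0001, 0.004, length.out = n * n), n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    cube[r, c, ] <- make_pixel(ax, amide = 1, noise_amp = noise_amp[r, c])
  }
  m <- hyperspec_map(cube, ax, list(sample_id = "cap"))
  p <- qc_params(pixel_cap = 10L)
  mask <- qc_mask(m, p)
  expect_identical(sum(mask$accepted), as.integer(n * n))
  capped <- rank_and_cap(m, mask, p)
  expect_identical(sum(capped$accepted), 10L)
  expect_identical(attr(capped, "n_accepted_raw"), as.integer(n * n))
  # exactly the 10 lowest noise amplitudes survive
  kept <- which(capped$accepted)
  expect_setequal(kept, order(as.vector(noise_amp))[1:10])
  # output is a subset of the input mask
  expect_true(all(mask$accepted[capped$accepted]))
  # cap not binding: everything kept
  loose <- rank_and_cap(m, mask, qc_params(pixel_cap = 500L))
  expect_identical(sum(loose$accepted), as.integer(n * n))
})

test_that("ties at the cap boundary break by (row, col) lexicographic order", {
  ax <- seq(3900, 900, by = -2)
  cube <- array(0, dim = c(2, 2, length(ax)))
  for (r in 1:2) for (c in 1:2) {
    cube[r, c, ] <- make_pixel(ax, amide = 1, noise_amp = 0.001)
  }
  m <- hyperspec_map(cube, ax, list(sample_id = "tie"))
  p <- qc_params(pixel_cap = 2L)
  capped <- rank_and_cap(m, qc_mask(m, p), p)
  expect_identical(sum(capped$accepted), 2L)
  expect_true(capped$accepted[1, 1])
  expect_true(capped$accepted[1, 2])  # (1,1) then (1,2) in (row, col) order
})

test_that("qc_cohort accounts for retained pixels per image", {
  cfg <- tiny_config(n_rows = 6L, n_cols = 6L, n_points = 1024L)
  maps <- list(a = generate_map(cfg, 0, 14, "M001", seed = 1L),
               b = generate_map(cfg, 1, 14, "M002", seed = 2L))
  res <- qc_cohort(maps, qc_params(pixel_cap = 20L))
  expect_identical(res$summary$sample_id, c("a", "b"))
  expect_true(all(res$summary$n_retained <= 20L))
  expect_true(all(res$summary$n_retained <= res$summary$n_accepted_raw))
})
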