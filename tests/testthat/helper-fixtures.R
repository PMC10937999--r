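# Shared fixtures, generated in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast config: 8x8 detector, 2 cm^-1 spacing; overrides win
tiny_config <- function(...) {
  args <- list(n_mice_per_group = 1L, doses = c(0, 1), days = 14L,
               n_rows = 8L, n_cols = 8L, n_points = 1501L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# noise-free variant for analytic oracles
clean_config <- function(...) {
  args <- list(noise_sd = 0, dead_pixel_rate = 0, animal_effect_sd = 0,
               pixel_scale_sd = 0, hetero_coef = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(tiny_config, args)
}

tiny_axis <- function(n = 1501L) seq(3900, 900, length.out = n)

# analytic Gaussian mixture (independent of the package's internals beyond
# the band table contract)
oracle_band_sum <- function(axis, table = synth_band_table(),
                            shift = FALSE, day_mult = 1) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(table))) {
    centre <- table$position[i]
    amp <- table$amplitude[i]
    if (shift) {
      if (!is.na(table$shift_to[i])) centre <- table$shift_to[i]
      if (table$position[i] != 1553) {
        sgn <- if (table$direction[i] == "up") 1 else -1
        amp <- amp + sgn * table$delta_intensity[i] * 1e-4 * table$sigma[i]^2 * day_mult
      }
    }
    out <- out + amp * exp(-(axis - centre)^2 / (2 * table$sigma[i]^2))
  }
  out
}

# a flat map with every pixel equal to `spectrum`
constant_map <- function(spectrum, axis, n_rows = 6L, n_cols = 6L,
                         sample_id = "const") {
  cube <- array(rep(spectrum, each = n_rows * n_cols),
                dim = c(n_rows, n_cols, length(axis)))
  hyperspec_map(cube, axis, list(sample_id = sample_id, mouse_id = "M000",
                                 dose_gy = 0, day = 14L, split = "train"))
}

# preprocessed two-class pool from the clean (noise-free) tiny cohort
clean_pool <- function() {
  cached("clean_pool", {
    cfg <- clean_config()
    m0 <- generate_map(cfg, 0, 14, "M001", seed = 7L)
    m1 <- generate_map(cfg, 1, 14, "M002", seed = 8L)
    pool_pixels(list(preprocess_map(m0), preprocess_map(m1)))
  })
}

# simple separable 2-D toy problem for classifier contracts
toy_xy <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, mean = -2, sd = 0.3), n / 2, 2),
             matrix(rnorm(n, mean = 2, sd = 0.3), n / 2, 2))
  colnames(x) <- c("1500.0000", "1400.0000")
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}
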