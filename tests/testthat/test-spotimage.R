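test_that("background generation honors mean, spread and determinism", {
  flat <- generate_background(256, 256, noise_mean = 100, noise_std = 0)
  expect_true(all(flat == 100))

  bg <- generate_background(256, 256, 100, 10, seed = 7)
  expect_gte(sd(bg), 9.5)
  expect_lte(sd(bg), 10.5)

  expect_identical(bg, generate_background(256, 256, 100, 10, seed = 7))
  expect_false(identical(bg, generate_background(256, 256, 100, 10, seed = 8)))

  tex <- generate_background(256, 256, 100, 10, texture_scale = 8, seed = 3)
  expect_gte(sd(tex), 9.5)
  expect_lte(sd(tex), 10.5)

  expect_error(generate_background(4, 256), "at least 16")
})

test_that("spot placement respects count, spacing and border margin", {
  cfg <- synth_config(n_spots = 0L)
  expect_equal(nrow(sample_spot_locations(cfg, 256, 256)), 0L)

  cfg2 <- synth_config(n_spots = 2L, min_nnd = 50, seed = 1L)
  p2 <- sample_spot_locations(cfg2, 256, 256)
  expect_gte(sqrt(diff(p2$x)^2 + diff(p2$y)^2), 50)

  cfg3 <- synth_config(n_spots = 100L, min_nnd = 15, sigma = 1.5, seed = 2L)
  p3 <- sample_spot_locations(cfg3, 512, 512)
  expect_equal(nrow(p3), 100L)
  d <- as.matrix(dist(p3)); diag(d) <- Inf
  expect_gte(min(d), 15)  # brute-force all-pairs check
  expect_true(all(p3$x >= 4.5 & p3$x <= 512 - 1 - 4.5))
  expect_true(all(p3$y >= 4.5 & p3$y <= 512 - 1 - 4.5))

  infeasible <- synth_config(n_spots = 200L, min_nnd = 60, seed = 1L)
  expect_error(sample_spot_locations(infeasible, 256, 256), "packing")
})

test_that("rendering calibrates SNR and preserves the background", {
  bg <- generate_background(128, 128, 100, 10, seed = 11)
  cfg <- synth_config(n_spots = 1L, snr_mean = 15, snr_spread = 0,
                      sigma = 1.5, seed = 11)
  r0 <- render_spots(bg, data.frame(x = numeric(0), y = numeric(0)),
                     synth_config(n_spots = 0L))
  expect_identical(r0$image, bg)

  loc <- data.frame(x = 64, y = 64)
  r1 <- render_spots(bg, loc, cfg)
  snr <- measure_snr(r1$image, 64, 64, 1.5)
  expect_gte(snr, 13.5)
  expect_lte(snr, 16.5)
  expect_identical(bg, generate_background(128, 128, 100, 10, seed = 11))
})

test_that("noiseless renders recover the requested sigma to 0.1%", {
  bg <- matrix(50, 96, 96)
  cfg <- synth_config(n_spots = 1L, snr_mean = 40, snr_spread = 0, sigma = 2,
                      seed = 1L)
  r <- render_spots(bg, data.frame(x = 47.3, y = 45.8), cfg)
  fit <- fit_gaussian_sigma(r$image, 47, 46)
  expect_false(fit$flagged)
  expect_lt(abs(fit$sigma - 2) / 2, 1e-3)
  expect_lt(abs(fit$x0 - 47.3), 0.05)
  expect_lt(abs(fit$y0 - 45.8), 0.05)
})

test_that("SNR measurement matches its analytic construction", {
  set.seed(42)
  img <- matrix(rnorm(160 * 160, 100, 10), 160, 160)
  # analytic Gaussian, amplitude 50 on noise sd 10 -> SNR ~ 5
  xs <- 0:159
  g <- 50 * exp(-outer((xs - 80)^2, (xs - 80)^2, "+") / (2 * 2^2))
  snr <- measure_snr(img + t(g), 80, 80, 2)
  expect_gt(snr, 4.5)
  expect_lt(snr, 5.5)

  expect_equal(measure_snr(matrix(7, 64, 64), 32, 32, 2), 0)

  # scale invariance of the ratio definition
  snr2 <- measure_snr(2 * (img + t(g)), 80, 80, 2)
  expect_lt(abs(snr2 - snr) / snr, 1e-6)
})

test_that("image inversion is affine and annihilates constants", {
  expect_true(all(invert_image(matrix(3.5, 10, 10)) == 0))
  set.seed(1)
  im <- matrix(runif(100, 0, 50), 10, 10)
  inv2 <- invert_image(invert_image(im))
  expect_equal(diff(as.vector(inv2)), diff(as.vector(im)))
})

test_that("simulation is deterministic end to end given a config", {
  s1 <- simulate_spot_image(synth_config(n_spots = 20L, seed = 9), 128, 128)
  s2 <- simulate_spot_image(synth_config(n_spots = 20L, seed = 9), 128, 128)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
})

test_that("SNR fidelity holds in the mean over many rendered spots", {
  for (target in c(5, 15)) {
    sim <- simulate_spot_image(
      synth_config(n_spots = 50L, snr_mean = target, snr_spread = 0,
                   min_nnd = 20, seed = 100 + target),
      width = 400, height = 400)
    snrs <- vapply(seq_len(50), function(i) {
      measure_snr(sim$image, sim$truth$x[i], sim$truth$y[i],
                  sim$truth$sigma[i])
    }, numeric(1))
    expect_lt(abs(mean(snrs) - target) / target, 0.10)
  }
})

test_that("truth tables round-trip through CSV", {
  sim <- simulate_spot_image(synth_config(n_spots = 5L, seed = 4), 128, 128)
  f <- tempfile(fileext = ".csv")
  write_spot_csv(sim$truth, f)
  back <- read_spot_csv(f)
  expect_equal(back$x, sim$truth$x, tolerance = 1e-12)
  expect_equal(back$spot_id, sim$truth$spot_id)
})
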