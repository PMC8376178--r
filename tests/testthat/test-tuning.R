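test_that("Gaussian fits recover noiseless spot parameters within 1%", {
  bg <- matrix(10, 80, 80)
  cfg <- synth_config(n_spots = 1L, snr_mean = 100, snr_spread = 0,
                      sigma = 1.5, seed = 1L)
  img <- render_spots(bg, data.frame(x = 40.4, y = 39.7), cfg)$image
  f <- fit_gaussian_sigma(img, 40, 40)
  expect_false(f$flagged)
  expect_lt(abs(f$sigma - 1.5) / 1.5, 0.01)
  expect_lt(abs(f$amplitude - 100) / 100, 0.01)
  expect_lt(abs(f$offset - 10) / 10, 0.01)

  flat <- fit_gaussian_sigma(matrix(5, 64, 64), 32, 32)
  expect_true(flat$flagged)
  expect_equal(flat$amplitude, 0)

  # adding a constant shifts only the offset
  f2 <- fit_gaussian_sigma(img + 37, 40, 40)
  expect_lt(abs(f2$sigma - f$sigma), 1e-6)
  expect_lt(abs(f2$amplitude - f$amplitude), 1e-4)
  expect_lt(abs(f2$offset - f$offset - 37), 1e-4)
})

test_that("extracted parameters bracket the true sigma range", {
  sigmas <- rep(c(1, 1.5, 2), length.out = 60)
  sim <- simulate_spot_image(
    synth_config(n_spots = 60L, snr_mean = 15, snr_spread = 0,
                 sigma = sigmas, min_nnd = 14, seed = 8), 300, 300)
  p <- extract_spot_params(sim$image, sim$truth)
  expect_lt(abs(p$sigma_min - 1) / 1, 0.25)
  expect_lt(abs(p$sigma_max - 2) / 2, 0.25)
  expect_lte(p$sigma_min, 1.05)
  expect_gte(p$sigma_max, 1.95)

  # argmax contract: the returned threshold is grid-optimal when re-scored
  score <- p$grid$precision * p$grid$recall
  best_score <- score[p$grid$threshold == p$intensity_threshold]
  expect_true(all(score <= best_score + 1e-12))

  expect_error(extract_spot_params(sim$image, sim$truth[1:2, ]),
               "insufficient")
})

test_that("the staircase image yields one peak at high stringency", {
  img <- matrix(1, 64, 64)
  xs <- c(10, 20, 30, 40, 50)
  hts <- c(10, 20, 30, 40, 50)
  for (i in seq_along(xs)) img[32, xs[i] + 1] <- hts[i]
  pk_all <- local_max_peakfind(img, stringency = 0, min_distance = 2)
  expect_gte(nrow(pk_all), 3L)
  pk_top <- suppressWarnings(local_max_peakfind(img, stringency = 10,
                                                min_distance = 2))
  expect_equal(nrow(pk_top), 1L)
  expect_equal(pk_top$x, 50)
  expect_equal(pk_top$y, 31)

  blank <- local_max_peakfind(matrix(2, 32, 32), 0)
  expect_equal(nrow(blank), 0L)
})

test_that("detections are nested and non-increasing in stringency", {
  for (seed in 1:5) {
    sim <- simulate_spot_image(synth_config(n_spots = 20L, seed = seed),
                               160, 160)
    img <- gaussian_blur(sim$image, 1.5)
    prev <- NULL
    for (s in 0:6) {
      pk <- suppressWarnings(local_max_peakfind(img, stringency = s))
      if (!is.null(prev)) {
        expect_lte(nrow(pk), nrow(prev))
        expect_true(all(paste(pk$x, pk$y) %in% paste(prev$x, prev$y)))
      }
      prev <- pk
    }
  }
})

test_that("stringency tuning returns the grid optimum", {
  sim <- simulate_spot_image(synth_config(n_spots = 40L, seed = 12), 256, 256)
  img <- gaussian_blur(sim$image, 1.5)

  one <- tune_stringency(img, sim$truth, grid = 3L)
  expect_equal(one$best_stringency, 3L)

  tr <- tune_stringency(img, sim$truth, grid = 0:8)
  # brute-force re-evaluation of every grid point
  rescored <- vapply(0:8, function(s) {
    pk <- suppressWarnings(local_max_peakfind(img, stringency = s))
    m <- match_points(pk, sim$truth, threshold = 4)
    m$precision * m$recall
  }, numeric(1))
  expect_equal(tr$best_stringency, (0:8)[max(which(rescored == max(rescored)))])
  expect_equal(tr$precision_curve * tr$recall_curve, rescored)
  expect_gte(tr$best_precision * tr$best_recall, max(rescored) - 1e-12)
})

test_that("truth-tuned and consensus-tuned stringency perform alike", {
  diffs <- vapply(1:5, function(seed) {
    sim <- simulate_spot_image(synth_config(n_spots = 60L, min_nnd = 15,
                                            seed = seed), 300, 300)
    crowd <- simulate_crowd(sim$truth, 300, 300, n_workers = 25, seed = seed)
    consensus <- run_qc(crowd)$consensus
    img <- gaussian_blur(sim$image, 1.5)
    t_truth <- tune_stringency(img, sim$truth, grid = 0:8)
    t_cons <- tune_stringency(img, consensus, grid = 0:8)
    score_vs_truth <- function(s) {
      pk <- suppressWarnings(local_max_peakfind(img, stringency = s))
      m <- match_points(pk, sim$truth, threshold = 4)
      m$precision * m$recall
    }
    abs(score_vs_truth(t_truth$best_stringency) -
          score_vs_truth(t_cons$best_stringency))
  }, numeric(1))
  expect_true(all(diffs <= 0.05))
})

test_that("training curves are deterministic and plateau at full size", {
  sim <- simulate_spot_image(synth_config(n_spots = 40L, seed = 14), 256, 256)
  tc <- training_curve(sim$image, sim$truth, subset_sizes = c(10, 40),
                       n_reps = 3L, seed = 5)
  tc2 <- training_curve(sim$image, sim$truth, subset_sizes = c(10, 40),
                        n_reps = 3L, seed = 5)
  expect_identical(tc, tc2)

  # full-size subset equals tuning on the full truth, single repetition
  expect_equal(tc$n_reps[tc$size == 40], 1L)
  p_full <- extract_spot_params(sim$image, sim$truth)
  m_full <- match_points(detect_spots(sim$image, p_full), sim$truth,
                         threshold = 4)
  expect_equal(tc$mean_precision[tc$size == 40], m_full$precision)
  expect_equal(tc$mean_recall[tc$size == 40], m_full$recall)
})
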