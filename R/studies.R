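# Simulation studies characterizing the pipeline on synthetic data. These
# are the package's own validation experiments; the acceptance script and
# the test suite both run them.

#' QC direction study: stage-wise precision and recall on simulated crowds
#'
#' Repeats the standard QC experiment: a 300x300 synthetic field with 100
#' spots at mean SNR 15 annotated by 25 simulated workers under the
#' default worker model; consensus is scored against the simulation truth
#' at each QC stage (raw cluster centroids, after size thresholding,
#' after declumping).
#'
#' @param n_sims Number of seeded replicates.
#' @param seed Master seed.
#' @param n_spots,snr_mean,width,height,n_workers Study conditions.
#' @param threshold Correctness radius in pixels.
#' @return Data frame with one row per replicate (`precision_raw`,
#'   `recall_raw`, `precision_size`, `recall_size`, `precision_qc`,
#'   `recall_qc`).
#' @export
study_qc_direction <- function(n_sims = 50L, seed = 1L, n_spots = 100L,
                               snr_mean = 15, width = 300L, height = 300L,
                               n_workers = 25L, threshold = 4) {
  rows <- lapply(seq_len(n_sims), function(i) {
    s <- derive_seed(seed, paste0("qcdir", i))
    sim <- simulate_spot_image(
      synth_config(n_spots = n_spots, snr_mean = snr_mean, seed = s),
      width = width, height = height)
    crowd <- simulate_crowd(sim$truth, width, height, n_workers = n_workers,
                            seed = s)
    qc <- run_qc(crowd)
    cl <- qc$clusters$clusters
    m_raw <- match_points(cl[, c("x", "y")], sim$truth, threshold)
    m_size <- match_points(cl[qc$size$kept, c("x", "y")], sim$truth,
                           threshold)
    m_qc <- match_points(qc$consensus, sim$truth, threshold)
    data.frame(precision_raw = m_raw$precision, recall_raw = m_raw$recall,
               precision_size = m_size$precision,
               recall_size = m_size$recall,
               precision_qc = m_qc$precision, recall_qc = m_qc$recall)
  })
  do.call(rbind, rows)
}

#' Crop round-trip study: subdivision never loses or duplicates points
#'
#' For seeded synthetic images, subdivides the image, maps the truth into
#' every covering crop's displayed frame, reassembles with deduplication,
#' and checks that each truth point is recovered exactly once within the
#' deduplication radius.
#'
#' @param n_images Number of seeded replicates.
#' @param seed Master seed.
#' @param dedup_radius Merge radius in parent pixels.
#' @param display_width Displayed crop width.
#' @return Data frame per image: `n_truth`, `n_reassembled`, `n_matched`,
#'   `recovered` (all matched, no surplus).
#' @export
study_crop_roundtrip <- function(n_images = 50L, seed = 1L, dedup_radius = 2,
                                 display_width = 450L) {
  rows <- lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, paste0("crop", i))
    sim <- simulate_spot_image(synth_config(seed = s), 300, 300)
    crops <- recursive_subdivide(sim$image, sim$truth,
                                 display_width = display_width)
    pts <- lapply(crops, function(cr) map_to_crop(cr$spec, sim$truth))
    names(pts) <- vapply(crops, function(cr) cr$spec$crop_id, character(1))
    rec <- reassemble(pts, crops, dedup_radius = dedup_radius)
    m <- match_points(rec, sim$truth, threshold = dedup_radius)
    data.frame(n_truth = nrow(sim$truth), n_reassembled = nrow(rec),
               n_matched = m$tp,
               recovered = m$tp == nrow(sim$truth) &&
                 nrow(rec) == nrow(sim$truth))
  })
  do.call(rbind, rows)
}

#' Parameter recovery study: sigma bracketing and held-out detection
#'
#' For seeded synthetic images whose spots mix sigma 1, 1.5 and 2 px at
#' mean SNR 15, extracts detection parameters using the simulation truth
#' as the expert annotation, checks that the extracted sigma band
#' brackets the true range, and scores the tuned detector on a held-out
#' image generated with identical parameters.
#'
#' @param n_images Number of seeded replicates.
#' @param seed Master seed.
#' @param threshold Correctness radius in pixels.
#' @return Data frame per replicate: `sigma_min`, `sigma_max`,
#'   `brackets` (band contains `[1, 2]`), `precision`, `recall` on the
#'   held-out image.
#' @export
study_parameter_recovery <- function(n_images = 20L, seed = 1L,
                                     threshold = 4) {
  sig_mix <- rep(c(1, 1.5, 2), length.out = 60L)
  rows <- lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, paste0("param", i))
    cfg <- synth_config(n_spots = 60L, snr_mean = 15, sigma = sig_mix,
                        min_nnd = 14, seed = s)
    train <- simulate_spot_image(cfg, 300, 300)
    p <- extract_spot_params(train$image, train$truth,
                             correctness_threshold = threshold)
    cfg2 <- cfg; cfg2$seed <- derive_seed(s, "heldout")
    test <- simulate_spot_image(cfg2, 300, 300)
    m <- match_points(detect_spots(test$image, p), test$truth, threshold)
    data.frame(sigma_min = p$sigma_min, sigma_max = p$sigma_max,
               brackets = p$sigma_min <= 1 && p$sigma_max >= 2,
               precision = m$precision, recall = m$recall)
  })
  do.call(rbind, rows)
}

#' Stringency contract study: monotone counts and grid-optimal tuning
#'
#' On seeded synthetic images (matched-filtered before peak finding),
#' verifies that the detection count never increases with stringency and
#' that [tune_stringency()]'s reported optimum equals an independent
#' brute-force re-evaluation of every grid value.
#'
#' @param n_images Number of seeded replicates.
#' @param seed Master seed.
#' @param grid Stringency grid.
#' @return Data frame per image: `monotone`, `argmax_agrees`.
#' @export
study_stringency_contract <- function(n_images = 20L, seed = 1L,
                                      grid = 0:8) {
  rows <- lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, paste0("str", i))
    sim <- simulate_spot_image(synth_config(n_spots = 25L, seed = s),
                               180, 180)
    img <- gaussian_blur(sim$image, 1.5)
    counts <- vapply(grid, function(g) {
      nrow(suppressWarnings(local_max_peakfind(img, stringency = g)))
    }, integer(1))
    tr <- tune_stringency(img, sim$truth, grid = grid)
    rescored <- vapply(grid, function(g) {
      pk <- suppressWarnings(local_max_peakfind(img, stringency = g))
      m <- match_points(pk, sim$truth, threshold = 4)
      m$precision * m$recall
    }, numeric(1))
    brute_best <- grid[max(which(rescored == max(rescored)))]
    data.frame(monotone = all(diff(counts) <= 0L),
               argmax_agrees = tr$best_stringency == brute_best)
  })
  do.call(rbind, rows)
}

#' Training plateau study: how many ground-truth spots are enough
#'
#' On one 400x400 synthetic image with 200 spots, compares detector
#' performance tuned from 15-point ground-truth subsets (averaged over
#' repetitions) with performance tuned from the full truth.
#'
#' @param seed Master seed.
#' @param subset_size Small training size examined.
#' @param n_reps Random subsets drawn.
#' @return List with the [training_curve()] table and the
#'   precision/recall ratios of the subset to the full truth.
#' @export
study_training_plateau <- function(seed = 1L, subset_size = 15L,
                                   n_reps = 20L) {
  s <- derive_seed(seed, "train")
  sim <- simulate_spot_image(synth_config(n_spots = 200L, seed = s),
                             400, 400)
  tc <- training_curve(sim$image, sim$truth,
                       subset_sizes = c(subset_size, nrow(sim$truth)),
                       n_reps = n_reps, seed = s)
  full <- tc[tc$size == nrow(sim$truth), ]
  sub <- tc[tc$size == subset_size, ]
  list(curve = tc,
       precision_ratio = sub$mean_precision / full$mean_precision,
       recall_ratio = sub$mean_recall / full$mean_recall)
}

#' Simulator fidelity study: SNR calibration and sigma round trip
#'
#' Renders 60 spots per SNR target on noisy backgrounds and re-measures
#' their SNR; renders noiseless spots and re-fits their sigma.
#'
#' @param seed Master seed.
#' @param targets SNR targets examined.
#' @return List with `snr` (data frame `target, mean_measured,
#'   rel_error`) and `sigma_max_rel_error` (worst relative sigma error on
#'   noiseless renders).
#' @export
study_simulator_fidelity <- function(seed = 1L, targets = c(5, 10, 15)) {
  snr_rows <- lapply(targets, function(t) {
    s <- derive_seed(seed, paste0("snr", t))
    sim <- simulate_spot_image(
      synth_config(n_spots = 60L, snr_mean = t, snr_spread = 0,
                   min_nnd = 20, seed = s), 420, 420)
    meas <- vapply(seq_len(nrow(sim$truth)), function(i) {
      measure_snr(sim$image, sim$truth$x[i], sim$truth$y[i],
                  sim$truth$sigma[i])
    }, numeric(1))
    data.frame(target = t, mean_measured = mean(meas),
               rel_error = abs(mean(meas) - t) / t)
  })
  s2 <- derive_seed(seed, "sigma")
  cfg <- synth_config(n_spots = 12L, snr_mean = 20, snr_spread = 0,
                      sigma = rep(c(1, 1.5, 2, 2.5), 3L), min_nnd = 25,
                      noise_std = 0, seed = s2)
  sim2 <- simulate_spot_image(cfg, 300, 300)
  errs <- vapply(seq_len(nrow(sim2$truth)), function(i) {
    f <- fit_gaussian_sigma(sim2$image, sim2$truth$x[i], sim2$truth$y[i],
                            window_halfwidth = 10L)
    abs(f$sigma - sim2$truth$sigma[i]) / sim2$truth$sigma[i]
  }, numeric(1))
  list(snr = do.call(rbind, snr_rows), sigma_max_rel_error = max(errs))
}

#' Matching equivalence study: greedy vs maximum-cardinality matching
#'
#' Generates random spot-like matching instances (separated truth points;
#' jittered, thinned predictions with stray false positives) and compares
#' the greedy matcher's true-positive count with the maximum-cardinality
#' (augmenting-path) matcher's on each.
#'
#' @param n_instances Number of instances.
#' @param seed Master seed.
#' @param max_points Maximum points per side.
#' @return Data frame per instance: `tp_greedy`, `tp_optimal`, `agree`.
#' @export
study_matching_equivalence <- function(n_instances = 200L, seed = 1L,
                                       max_points = 12L) {
  rows <- with_seed(derive_seed(seed, "match"), {
    lapply(seq_len(n_instances), function(i) {
      nt <- sample(3:max_points, 1L)
      truth <- matrix(numeric(0), ncol = 2)
      while (nrow(truth) < nt) {
        p <- stats::runif(2, 0, 80)
        if (nrow(truth) == 0 ||
            min(sqrt((truth[, 1] - p[1])^2 + (truth[, 2] - p[2])^2)) >= 10) {
          truth <- rbind(truth, p)
        }
      }
      truth <- data.frame(x = truth[, 1], y = truth[, 2])
      keep <- stats::runif(nt) > 0.2
      pred <- data.frame(
        x = truth$x[keep] + stats::rnorm(sum(keep), 0, 2),
        y = truth$y[keep] + stats::rnorm(sum(keep), 0, 2))
      n_extra <- sample(0:2, 1L)
      if (n_extra > 0) {
        pred <- rbind(pred, data.frame(x = stats::runif(n_extra, 0, 80),
                                       y = stats::runif(n_extra, 0, 80)))
      }
      pred <- utils::head(pred, max_points)
      g <- match_points(pred, truth, 4, method = "greedy")$tp
      o <- match_points(pred, truth, 4, method = "optimal")$tp
      data.frame(tp_greedy = g, tp_optimal = o, agree = g == o)
    })
  })
  do.call(rbind, rows)
}
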