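#' Simulated annotator model
#'
#' Parameterizes a stochastic model of one crowdsourced annotator clicking
#' on spots in an image. The model captures the empirical behaviors that
#' matter for consensus QC: SNR-dependent detection (logistic curve, with
#' sub-pixel spots at half effective SNR), isotropic click jitter, uniform
#' false-positive clicks, a per-image click budget (detections are kept
#' preferentially when the budget binds), and marker-occlusion merging —
#' spot pairs closer than a fraction of the displayed image width may be
#' annotated with a single click near their midpoint, sometimes with an
#' extra click inside the pair region. All defaults are invented, plausible
#' settings for testing the QC pipeline; none is an empirical estimate.
#'
#' @param p_detect_midpoint SNR at which detection probability is 0.5.
#' @param p_detect_slope Logistic slope (> 0) in 1/SNR units.
#' @param click_jitter_sigma Click jitter standard deviation, pixels (>= 0).
#' @param fp_rate Expected false clicks per image (Poisson mean, >= 0).
#' @param click_budget Maximum clicks per worker per image (> 0); the
#'   empirical ceiling is around 120.
#' @param merge_radius_frac Fraction of the image width below which a spot
#'   pair may be merged into one click (in `[0, 1]`).
#' @param p_merge Probability a qualifying detected pair is merged.
#' @param p_multiclick Probability a merging worker adds a second click
#'   inside the merged pair's region.
#' @return List of class `worker_model`.
#' @export
worker_model <- function(p_detect_midpoint = 5, p_detect_slope = 1,
                         click_jitter_sigma = 1, fp_rate = 2,
                         click_budget = 120L, merge_radius_frac = 0.04,
                         p_merge = 0.6, p_multiclick = 0.3) {
  stopifnot(p_detect_slope > 0, click_jitter_sigma >= 0, fp_rate >= 0,
            click_budget > 0, merge_radius_frac >= 0, merge_radius_frac <= 1,
            p_merge >= 0, p_merge <= 1, p_multiclick >= 0, p_multiclick <= 1)
  structure(list(p_detect_midpoint = p_detect_midpoint,
                 p_detect_slope = p_detect_slope,
                 click_jitter_sigma = click_jitter_sigma,
                 fp_rate = fp_rate, click_budget = as.integer(click_budget),
                 merge_radius_frac = merge_radius_frac, p_merge = p_merge,
                 p_multiclick = p_multiclick),
            class = "worker_model")
}

# Detection probability for a spot: logistic in effective SNR, where spots
# narrower than 1 px have their SNR halved (small spots are harder to see).
detect_prob <- function(snr, sigma, model) {
  eff <- ifelse(sigma < 1, 0.5 * snr, snr)
  stats::plogis((eff - model$p_detect_midpoint) * model$p_detect_slope)
}

#' Simulate one annotator on one image
#'
#' Applies the [worker_model()] to a ground-truth spot table: per-spot
#' Bernoulli detection on the logistic SNR curve; merged clicks for
#' detected pairs closer than `merge_radius_frac * image_width` (each spot
#' participates in at most one merge, closest pairs first); Gaussian click
#' jitter; Poisson false positives; truncation to the click budget with
#' detections kept preferentially; final click order randomized. The
#' stream is deterministic given `(seed, worker_id)` and independent of
#' other workers.
#'
#' @param truth Data frame with columns `x`, `y` and (optionally) `sigma`,
#'   `snr`; missing `snr` is treated as far above the detection midpoint.
#' @param image_width,image_height Image dimensions in pixels.
#' @param model A [worker_model()].
#' @param worker_id Character scalar.
#' @param image_id Character scalar recorded in the output.
#' @param seed Integer seed shared by the whole crowd.
#' @return Data frame `worker_id, image_id, x, y`, one row per click,
#'   all coordinates inside the image.
#' @export
simulate_worker <- function(truth, image_width, image_height, model,
                            worker_id, image_id = "img", seed = 1L) {
  n <- nrow(truth)
  sig <- if ("sigma" %in% names(truth)) truth$sigma else rep(2, n)
  snr <- if ("snr" %in% names(truth)) truth$snr else rep(Inf, n)
  with_seed(derive_seed(seed, worker_id), {
    clicks <- matrix(numeric(0), ncol = 2L)
    is_det <- logical(0)
    if (n > 0L) {
      detected <- stats::runif(n) < detect_prob(snr, sig, model)
      merged <- logical(n)
      det_clicks <- list()
      merge_radius <- model$merge_radius_frac * image_width
      if (merge_radius > 0 && sum(detected) >= 2L) {
        di <- which(detected)
        d <- cross_dist(truth[di, c("x", "y")], truth[di, c("x", "y")])
        d[upper.tri(d, diag = TRUE)] <- Inf
        pr <- which(d < merge_radius, arr.ind = TRUE)
        if (nrow(pr) > 0L) {
          pr <- pr[order(d[pr]), , drop = FALSE]
          for (k in seq_len(nrow(pr))) {
            i <- di[pr[k, 1L]]; j <- di[pr[k, 2L]]
            if (!merged[i] && !merged[j] && stats::runif(1) < model$p_merge) {
              merged[i] <- TRUE; merged[j] <- TRUE
              mid <- c((truth$x[i] + truth$x[j]) / 2,
                       (truth$y[i] + truth$y[j]) / 2)
              det_clicks[[length(det_clicks) + 1L]] <-
                mid + stats::rnorm(2L, 0, model$click_jitter_sigma)
              if (stats::runif(1) < model$p_multiclick) {
                # extra click inside the pair region: uniform along the
                # middle half of the segment, plus jitter
                tpos <- stats::runif(1, 0.25, 0.75)
                pt <- c(truth$x[i], truth$y[i]) * (1 - tpos) +
                  c(truth$x[j], truth$y[j]) * tpos
                det_clicks[[length(det_clicks) + 1L]] <-
                  pt + stats::rnorm(2L, 0, model$click_jitter_sigma)
              }
            }
          }
        }
      }
      for (i in which(detected & !merged)) {
        det_clicks[[length(det_clicks) + 1L]] <-
          c(truth$x[i], truth$y[i]) + stats::rnorm(2L, 0, model$click_jitter_sigma)
      }
      if (length(det_clicks) > 0L) {
        clicks <- do.call(rbind, det_clicks)
        is_det <- rep(TRUE, nrow(clicks))
      }
    }
    n_fp <- stats::rpois(1L, model$fp_rate)
    if (n_fp > 0L) {
      fp <- cbind(stats::runif(n_fp, 0, image_width - 1e-9),
                  stats::runif(n_fp, 0, image_height - 1e-9))
      clicks <- rbind(clicks, fp)
      is_det <- c(is_det, rep(FALSE, n_fp))
    }
    nc <- nrow(clicks)
    if (nc > 0L) {
      # budget: keep detections first (random subset if they alone exceed
      # it), then false positives fill the remainder; randomize order
      budget <- model$click_budget
      det_idx <- which(is_det); fp_idx <- which(!is_det)
      if (length(det_idx) > budget) {
        det_idx <- sort(sample(det_idx, budget))
      }
      keep <- c(det_idx, utils::head(fp_idx, max(0L, budget - length(det_idx))))
      keep <- sample(keep)
      clicks <- clicks[keep, , drop = FALSE]
      # clamp jittered clicks into the image
      clicks[, 1L] <- pmin(pmax(clicks[, 1L], 0), image_width - 1e-9)
      clicks[, 2L] <- pmin(pmax(clicks[, 2L], 0), image_height - 1e-9)
    }
    data.frame(worker_id = rep(as.character(worker_id), nrow(clicks)),
               image_id = rep(as.character(image_id), nrow(clicks)),
               x = clicks[, 1L] %||% numeric(0),
               y = clicks[, 2L] %||% numeric(0),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a crowd of annotators
#'
#' Concatenates [simulate_worker()] outputs for `n_workers` independent
#' annotators with worker ids `w01, w02, ...`; each worker's stream is
#' derived from `(seed, worker_id)`, so enlarging the crowd leaves
#' existing workers' clicks unchanged.
#'
#' @inheritParams simulate_worker
#' @param n_workers Number of annotators (>= 1); crowdsourced runs
#'   typically use 20-30.
#' @return Data frame of class `annotation_set` with columns
#'   `annotation_id, worker_id, image_id, x, y`.
#' @export
simulate_crowd <- function(truth, image_width, image_height,
                           model = worker_model(), n_workers = 25L,
                           image_id = "img", seed = 1L) {
  if (n_workers < 1L) stop("`n_workers` must be at least 1", call. = FALSE)
  ids <- sprintf("w%02d", seq_len(n_workers))
  out <- do.call(rbind, lapply(ids, function(w) {
    simulate_worker(truth, image_width, image_height, model, w,
                    image_id = image_id, seed = seed)
  }))
  out <- cbind(annotation_id = sprintf("a%05d", seq_len(nrow(out))), out)
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' Write an annotation set as CSV
#'
#' Quanti.us-like dialect: `annotation_id,worker_id,image_id,x,y`,
#' coordinates 0-based.
#'
#' @param annos Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(annos, path) {
  utils::write.csv(
    annos[, c("annotation_id", "worker_id", "image_id", "x", "y")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
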