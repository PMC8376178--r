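#' Fit an isotropic 2-D Gaussian to a spot
#'
#' Least-squares fit of `offset + A * exp(-r^2 / (2 sigma^2))` in a square
#' window around `(x, y)`, with the center refined within +/- 2 px of the
#' brightest pixel near the click. Used to estimate spot size from expert
#' clicks and to measure amplitudes for SNR. On non-convergence the
#' result is flagged and sigma falls back to a second-moment estimate.
#'
#' @param img Numeric matrix.
#' @param x,y Approximate spot center (0-based pixels).
#' @param window_halfwidth Window half-width in pixels (>= 3).
#' @return List `sigma`, `amplitude`, `offset`, `x0`, `y0` (refined
#'   center), `flagged` (TRUE when the fit failed or found no signal).
#' @export
fit_gaussian_sigma <- function(img, x, y, window_halfwidth = 8L) {
  assert_image(img)
  stopifnot(window_halfwidth >= 3L)
  w <- img_width(img); h <- img_height(img)
  r <- window_halfwidth
  cols <- max(0, round(x) - r):min(w - 1, round(x) + r)
  rows <- max(0, round(y) - r):min(h - 1, round(y) + r)
  win <- img[rows + 1L, cols + 1L, drop = FALSE]
  offset0 <- stats::median(win)
  # refine center: brightest pixel within +/- 2 px of the click
  nc <- cols[cols >= x - 2 & cols <= x + 2]
  nr <- rows[rows >= y - 2 & rows <= y + 2]
  near <- img[nr + 1L, nc + 1L, drop = FALSE]
  pk <- which(near == max(near), arr.ind = TRUE)[1L, ]
  x0 <- nc[pk[2L]]; y0 <- nr[pk[1L]]
  amp0 <- max(near) - offset0

  cc <- rep(cols, each = length(rows))
  rr <- rep(rows, times = length(cols))
  z <- as.vector(win)
  second_moment_sigma <- function() {
    wgt <- pmax(z - offset0, 0)
    if (sum(wgt) <= 0) return(NA_real_)
    r2 <- (cc - x0)^2 + (rr - y0)^2
    sqrt(sum(wgt * r2) / sum(wgt) / 2)
  }
  if (amp0 <= 1e-12 || stats::sd(z) < 1e-12) {
    return(list(sigma = second_moment_sigma(), amplitude = 0,
                offset = offset0, x0 = x0, y0 = y0, flagged = TRUE))
  }
  dat <- data.frame(cc = cc, rr = rr, z = z)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ off + A * exp(-((cc - cx)^2 + (rr - cy)^2) / (2 * sg^2)),
      data = dat,
      start = list(off = offset0, A = amp0, cx = x0, cy = y0,
                   sg = max(1, second_moment_sigma() %||% 1.5)),
      lower = c(off = -Inf, A = 0, cx = x0 - 2, cy = y0 - 2, sg = 0.3),
      upper = c(off = Inf, A = Inf, cx = x0 + 2, cy = y0 + 2,
                sg = 2 * window_halfwidth),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(sigma = second_moment_sigma(), amplitude = amp0,
                offset = offset0, x0 = x0, y0 = y0, flagged = TRUE))
  }
  cf <- stats::coef(fit)
  # a sigma pinned at its box bound means the window holds no resolvable
  # spot (e.g. the click sits on background); flag such fits
  pinned <- cf["sg"] >= 2 * window_halfwidth - 1e-6 || cf["sg"] <= 0.3 + 1e-6
  list(sigma = unname(cf["sg"]), amplitude = unname(cf["A"]),
       offset = unname(cf["off"]), x0 = unname(cf["cx"]),
       y0 = unname(cf["cy"]), flagged = unname(pinned))
}

#' Extract spot-detection parameters from annotated examples
#'
#' Fits a Gaussian to every annotated spot; the sigma band for detection
#' is the fitted range with 10% guard margins (`sigma_max` = largest
#' fitted sigma + 10%, `sigma_min` = smallest - 10%, floored at 0.5 px) —
#' annotators mark spot centers, not extents, so the margins absorb fit
#' spread. The intensity threshold is then chosen from a geometric grid
#' (default 50 points over the detector's response range) to maximize
#' precision x recall of [log_detect()] against the annotated points,
#' ties broken toward the larger threshold (favoring precision: better to
#' miss spots than to detect false ones). Because the threshold is a
#' lower bound on the brightness of a detectable spot, candidate
#' thresholds are capped 10% below the dimmest annotated spot's response
#' (the brightness analog of the sigma guard margins), so a sparse
#' annotation sample cannot push the threshold above real spots.
#'
#' @param img Numeric matrix (typically pre-processed, see
#'   [preprocess_stack()]).
#' @param expert_points Data frame of annotated spot centers (`x`, `y`),
#'   at least 3.
#' @param threshold_grid Candidate intensity thresholds; `NULL` builds
#'   the default geometric grid.
#' @param n_scales Scales for [log_detect()].
#' @param correctness_threshold Match radius in pixels.
#' @param window_halfwidth Passed to [fit_gaussian_sigma()].
#' @return List of class `detection_params`: `sigma_min`, `sigma_max`,
#'   `intensity_threshold`, `n_scales`, plus the evaluated `grid` with
#'   precision/recall per threshold.
#' @export
extract_spot_params <- function(img, expert_points, threshold_grid = NULL,
                                n_scales = 10L, correctness_threshold = 4,
                                window_halfwidth = 8L) {
  expert_points <- as_points(expert_points)
  if (nrow(expert_points) < 3L) {
    stop("insufficient annotations: need at least 3 expert points", call. = FALSE)
  }
  fits <- lapply(seq_len(nrow(expert_points)), function(i) {
    fit_gaussian_sigma(img, expert_points$x[i], expert_points$y[i],
                       window_halfwidth = window_halfwidth)
  })
  sig <- vapply(fits, function(f) f$sigma, numeric(1))
  ok <- !vapply(fits, function(f) f$flagged, logical(1)) & is.finite(sig)
  if (sum(ok) < 3L) {
    stop("insufficient annotations: fewer than 3 spots could be fitted", call. = FALSE)
  }
  sigma_min <- max(0.5, min(sig[ok]) * 0.9)
  sigma_max <- max(sig[ok]) * 1.1
  det0 <- log_detect(img, sigma_min, sigma_max, n_scales = n_scales,
                     threshold = 0)
  if (nrow(det0) == 0L) {
    warning("no detector responses; threshold set to 0", call. = FALSE)
    return(structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                          intensity_threshold = 0, n_scales = n_scales,
                          grid = NULL),
                     class = "detection_params"))
  }
  if (is.null(threshold_grid)) {
    hi <- max(det0$response)
    threshold_grid <- exp(seq(log(hi / 1000), log(hi), length.out = 50L))
  }
  # the threshold is a lower bound on the brightness of a detectable
  # spot: it must admit every annotated spot. Candidates are therefore
  # capped 10% below the response of the dimmest detection matched to an
  # expert point -- the annotations are a finite sample of the brightness
  # range, and the guard margin (mirroring the sigma margins) admits
  # unannotated spots of the same brightness class. This also keeps
  # sparse annotation samples from driving the threshold up.
  m0 <- match_points(det0[, c("x", "y")], expert_points,
                     threshold = correctness_threshold)
  if (nrow(m0$pairs) > 0L) {
    cap <- 0.9 * min(det0$response[m0$pairs$pred])
    capped <- threshold_grid[threshold_grid <= cap]
    threshold_grid <- unique(sort(c(capped, cap)))
  }
  # thresholding a LoG detection set is equivalent to re-running the
  # detector at that threshold (pruning only ever keeps the stronger of an
  # overlapping pair), so the grid sweep reuses one detector pass
  pr <- t(vapply(threshold_grid, function(t) {
    d <- det0[det0$response >= t, c("x", "y"), drop = FALSE]
    m <- match_points(d, expert_points, threshold = correctness_threshold)
    c(precision = m$precision, recall = m$recall)
  }, numeric(2)))
  score <- pr[, 1L] * pr[, 2L]
  best <- max(which(score == max(score)))  # ties -> larger threshold
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 intensity_threshold = threshold_grid[best],
                 n_scales = n_scales,
                 grid = data.frame(threshold = threshold_grid,
                                   precision = pr[, 1L], recall = pr[, 2L])),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf("Detection parameters: sigma in [%.3g, %.3g] px, intensity threshold %.4g (%d scales)\n",
              x$sigma_min, x$sigma_max, x$intensity_threshold, x$n_scales))
  invisible(x)
}

#' Detect spots with extracted parameters
#'
#' @param img Numeric matrix.
#' @param params A [extract_spot_params()] result.
#' @return [log_detect()] output.
#' @export
detect_spots <- function(img, params) {
  log_detect(img, params$sigma_min, params$sigma_max,
             n_scales = params$n_scales,
             threshold = params$intensity_threshold)
}

#' Local-maximum peak finder with a stringency knob
#'
#' An integer `stringency` controls the intensity cutoff used to accept a
#' peak. The cutoff is chosen on the spot-count-versus-cutoff curve: a
#' uniform grid of candidate cutoffs spans the local-maximum intensity
#' range, runs of cutoffs yielding the same count form plateaus, and the
#' base cutoff is the start of the longest stable plateau (where the
#' detected count is least sensitive to the cutoff). Stringency `s`
#' selects the cutoff `s` plateaus above the base; the detected count is
#' therefore non-increasing in `s`. This plateau mechanism is a
#' scale-invariant reconstruction of the stringency knob of common
#' local-max peak finders, not a clone of any implementation.
#'
#' @param img Numeric matrix.
#' @param stringency Integer >= 0; values beyond the available plateaus
#'   are clamped with a warning.
#' @param min_distance Minimum separation between accepted peaks, pixels
#'   (>= 1); the brighter peak wins.
#' @param n_cutoffs Size of the cutoff grid.
#' @return Data frame `x, y, intensity` (0-based coordinates), brightest
#'   first, with attribute `"cutoff"`.
#' @export
local_max_peakfind <- function(img, stringency = 0L, min_distance = 2,
                               n_cutoffs = 100L) {
  assert_image(img)
  stopifnot(stringency >= 0, min_distance >= 1)
  lm <- is_local_max_2d(img)
  # exclude flat plateaus of constant images: require above-global-min
  lm <- lm & (img > min(img))
  idx <- which(lm, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
    attr(out, "cutoff") <- NA_real_
    return(out)
  }
  ints <- img[idx]
  lo <- min(ints); hi <- max(ints)
  cutoffs <- if (hi > lo) seq(lo, hi, length.out = n_cutoffs) else lo
  counts <- vapply(cutoffs, function(cv) sum(ints >= cv), integer(1))
  # plateaus: maximal runs of equal count along the cutoff grid
  runs <- rle(counts)
  starts <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
  base <- which.max(runs$lengths)  # longest plateau; ties -> lowest cutoff
  target <- base + stringency
  if (target > length(runs$values)) {
    warning("stringency beyond available cutoffs; clamped to maximum", call. = FALSE)
    target <- length(runs$values)
  }
  cutoff <- cutoffs[starts[target]]
  sel <- which(ints >= cutoff)
  ord <- sel[order(-ints[sel])]
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) { keep <- i; next }
    d2 <- (idx[keep, 2L] - idx[i, 2L])^2 + (idx[keep, 1L] - idx[i, 1L])^2
    if (all(d2 >= min_distance^2)) keep <- c(keep, i)
  }
  out <- data.frame(x = idx[keep, 2L] - 1, y = idx[keep, 1L] - 1,
                    intensity = ints[keep])
  attr(out, "cutoff") <- cutoff
  out
}

#' Tune the peak-finder stringency against ground truth
#'
#' Runs [local_max_peakfind()] at every stringency in `grid`, matches the
#' peaks to `truth_points` under the correctness radius, and returns the
#' full precision/recall curves plus the stringency maximizing
#' precision x recall (ties broken toward the higher stringency,
#' favoring precision).
#'
#' @param img Numeric matrix.
#' @param truth_points Data frame (`x`, `y`) used as ground truth —
#'   expert annotations, QC consensus, or simulation truth.
#' @param grid Integer stringencies to evaluate.
#' @param correctness_threshold Match radius in pixels.
#' @param min_distance Passed to [local_max_peakfind()].
#' @return List of class `tuning_result`: `grid`, `precision_curve`,
#'   `recall_curve`, `best_stringency`, `best_precision`, `best_recall`.
#' @export
tune_stringency <- function(img, truth_points, grid = 0:20,
                            correctness_threshold = 4, min_distance = 2) {
  stopifnot(length(grid) >= 1, nrow(truth_points) >= 1)
  truth_points <- as_points(truth_points)
  pr <- t(vapply(grid, function(s) {
    pk <- suppressWarnings(local_max_peakfind(img, stringency = s,
                                              min_distance = min_distance))
    m <- match_points(pk, truth_points, threshold = correctness_threshold)
    c(m$precision, m$recall)
  }, numeric(2)))
  score <- pr[, 1L] * pr[, 2L]
  best <- max(which(score == max(score)))
  structure(list(grid = grid, precision_curve = pr[, 1L],
                 recall_curve = pr[, 2L], best_stringency = grid[best],
                 best_precision = pr[best, 1L], best_recall = pr[best, 2L],
                 correctness_threshold = correctness_threshold),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Stringency tuning over %d values: best stringency %d (precision %.3f, recall %.3f)\n",
              length(x$grid), x$best_stringency, x$best_precision,
              x$best_recall))
  invisible(x)
}

#' @export
plot.tuning_result <- function(x, ...) {
  graphics::plot(x$grid, x$precision_curve, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "stringency",
                 ylab = "precision / recall", ...)
  graphics::lines(x$grid, x$recall_curve, type = "b", pch = 1, lty = 2)
  graphics::abline(v = x$best_stringency, col = "grey60", lty = 3)
  graphics::legend("bottomleft", legend = c("precision", "recall"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Ground-truth training curve for parameter extraction
#'
#' How many annotated spots are enough? For each subset size, draws
#' `n_reps` random subsets of the truth table, extracts detection
#' parameters from each subset alone, detects spots on the same image,
#' and scores precision/recall against the full truth. Means and
#' standard deviations per size trace the training curve; performance
#' typically plateaus by 15-20 annotations.
#'
#' @param img Numeric matrix.
#' @param truth_points Full ground-truth table (`x`, `y`).
#' @param subset_sizes Integer vector of sizes (each <= number of truth
#'   points).
#' @param n_reps Random subsets per size (a size equal to the full truth
#'   uses a single reptition).
#' @param seed Integer seed; the whole curve is deterministic given it.
#' @param correctness_threshold Match radius in pixels.
#' @return Data frame `size, n_reps, mean_precision, sd_precision,
#'   mean_recall, sd_recall`.
#' @export
training_curve <- function(img, truth_points, subset_sizes = c(5, 10, 15, 20),
                           n_reps = 20L, seed = 1L,
                           correctness_threshold = 4) {
  truth_points <- as_points(truth_points)
  n <- nrow(truth_points)
  stopifnot(all(subset_sizes <= n), all(subset_sizes >= 3))
  rows <- lapply(subset_sizes, function(sz) {
    reps <- if (sz == n) 1L else n_reps
    pr <- t(vapply(seq_len(reps), function(rep) {
      sub <- with_seed(derive_seed(seed, paste0("tc", sz, "_", rep)), {
        truth_points[sample.int(n, sz), , drop = FALSE]
      })
      params <- extract_spot_params(img, sub,
                                    correctness_threshold = correctness_threshold)
      det <- detect_spots(img, params)
      m <- match_points(det[, c("x", "y")], truth_points,
                        threshold = correctness_threshold)
      c(m$precision, m$recall)
    }, numeric(2)))
    data.frame(size = sz, n_reps = reps,
               mean_precision = mean(pr[, 1L]),
               sd_precision = if (reps > 1L) stats::sd(pr[, 1L]) else 0,
               mean_recall = mean(pr[, 2L]),
               sd_recall = if (reps > 1L) stats::sd(pr[, 2L]) else 0)
  })
  do.call(rbind, rows)
}
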