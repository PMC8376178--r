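# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths.

# Maximum-cardinality matching by exhaustive recursion (feasible for a
# handful of points): upper bound on the number of radius-compatible
# one-to-one pairs.
bf_max_matching <- function(pred, truth, threshold) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0L || nt == 0L) return(0L)
  d <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
  adj <- lapply(seq_len(np), function(i) which(d[i, ] <= threshold))
  rec <- function(i, used) {
    if (i > np) return(0L)
    best <- rec(i + 1L, used)  # skip pred i
    for (t in adj[[i]]) {
      if (!used[t]) {
        used[t] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[t] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(nt))
}

# Brute-force 1-D 2-means over all split points of the sorted values:
# returns the optimal threshold (midpoint between the two cluster means'
# boundary... the midpoint of the cluster means) minimizing within-cluster
# sum of squares.
bf_two_means_split <- function(v) {
  v <- sort(v)
  n <- length(v)
  best <- NULL
  for (s in 1:(n - 1L)) {
    lo <- v[1:s]; hi <- v[(s + 1L):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(ss = ss, threshold = (mean(lo) + mean(hi)) / 2)
    }
  }
  best$threshold
}

# Dense-scan LoG oracle: direct spatial convolution (replicated borders)
# with the same discrete Gaussian kernel definition (half-width
# ceiling(3*sigma)), negative 4-neighbor Laplacian, sigma^2
# normalization; exhaustive (x, y, scale) local-maximum scan and the
# stronger-wins overlap prune. Shares only the mathematical definition
# with the package, not its code path.
oracle_log_detect <- function(img, sigma_min, sigma_max, n_scales, threshold) {
  pad_rep <- function(m, k) {
    m <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), , drop = FALSE]
    m[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
  }
  conv <- function(m, ker) {
    hw <- (nrow(ker) - 1L) %/% 2L
    p <- pad_rep(m, hw)
    out <- matrix(0, nrow(m), ncol(m))
    for (di in -hw:hw) for (dj in -hw:hw) {
      out <- out + ker[di + hw + 1L, dj + hw + 1L] *
        p[(seq_len(nrow(m))) + hw + di, (seq_len(ncol(m))) + hw + dj]
    }
    out
  }
  gk <- function(sigma) {
    hw <- ceiling(3 * sigma)
    g <- exp(-(outer((-hw:hw)^2, (-hw:hw)^2, "+")) / (2 * sigma^2))
    g / sum(g)
  }
  lap <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
  sigmas <- if (n_scales == 1L) sigma_min else
    exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales))
  resp <- lapply(sigmas, function(s) s^2 * conv(conv(img, gk(s)), lap))
  h <- nrow(img); w <- ncol(img)
  det <- NULL
  for (s in seq_along(sigmas)) {
    for (i in 1:h) for (j in 1:w) {
      v <- resp[[s]][i, j]
      if (v <= threshold) next
      ok <- TRUE
      for (ss in max(1, s - 1):min(length(sigmas), s + 1)) {
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > h || jj < 1 || jj > w) next
          if (ss == s && di == 0 && dj == 0) next
          if (resp[[ss]][ii, jj] > v) ok <- FALSE
        }
      }
      if (ok) det <- rbind(det, c(j - 1, i - 1, sigmas[s], v))
    }
  }
  if (is.null(det)) {
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      response = numeric(0)))
  }
  det <- data.frame(x = det[, 1], y = det[, 2], sigma = det[, 3],
                    response = det[, 4])
  det <- det[order(-det$response, det$x, det$y), ]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ki <- which(keep)
    if (length(ki) == 0L) { keep[i] <- TRUE; next }
    dd <- sqrt((det$x[ki] - det$x[i])^2 + (det$y[ki] - det$y[i])^2)
    keep[i] <- all(dd >= sqrt(2) * pmax(det$sigma[ki], det$sigma[i]))
  }
  det[keep, ]
}

# Spot-like point geometry: separated truth points (minimum spacing above
# the correctness radius) and predictions derived from them by jitter,
# dropout and stray false positives. Mirrors the geometry the matcher
# meets in practice.
spot_like_points <- function(n, lo = 5, hi = 55, min_sep = 10) {
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n) {
    p <- runif(2, lo, hi)
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep) {
      pts <- rbind(pts, p)
    }
  }
  data.frame(x = pts[, 1], y = pts[, 2])
}

jittered_predictions <- function(truth, jitter = 2, p_drop = 0.2,
                                 n_extra = 1) {
  keep <- runif(nrow(truth)) > p_drop
  pred <- data.frame(x = truth$x[keep] + rnorm(sum(keep), 0, jitter),
                     y = truth$y[keep] + rnorm(sum(keep), 0, jitter))
  if (n_extra > 0) {
    pred <- rbind(pred, data.frame(x = runif(n_extra, 0, 60),
                                   y = runif(n_extra, 0, 60)))
  }
  pred
}

# Small simulated crowd on a simulated image, shared by QC tests.
make_sim_crowd <- function(seed, n_spots = 100L, width = 300L, height = 300L,
                           n_workers = 25L, snr_mean = 15, ...) {
  sim <- simulate_spot_image(
    synth_config(n_spots = n_spots, snr_mean = snr_mean, seed = seed, ...),
    width = width, height = height)
  crowd <- simulate_crowd(sim$truth, width, height, n_workers = n_workers,
                          seed = seed)
  list(sim = sim, crowd = crowd)
}
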