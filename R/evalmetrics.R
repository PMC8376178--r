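#' Match predicted points to ground truth under a correctness radius
#'
#' Builds a one-to-one matching between two 2-D point sets. A predicted
#' point counts as a true positive when it is paired with a truth point no
#' farther than `threshold` pixels away. The default `"greedy"` method
#' scans all candidate pairs in order of ascending distance and accepts a
#' pair when both endpoints are still unclaimed; `"optimal"` computes a
#' maximum-cardinality matching of the threshold graph by augmenting
#' paths. Both respect the radius; greedy is order-stable and fast and is
#' the package default.
#'
#' @param pred,truth Data frames (or 2-column matrices) with columns
#'   `x`, `y`.
#' @param threshold Correctness radius in pixels (> 0); default 4.
#' @param method `"greedy"` or `"optimal"`.
#' @return A list of class `match_result`: `tp`, `fp`, `fn`, `pairs`
#'   (data frame `pred`, `truth`, `distance`, 1-based row indices),
#'   `precision`, `recall`, `jaccard`, `threshold`. Conventions for empty
#'   sets: precision is 1 when nothing was predicted and nothing was
#'   missed, 0 when there are predictions but no matches; recall is 1 when
#'   there is no truth.
#' @examples
#' m <- match_points(data.frame(x = c(0, 10), y = c(0, 10)),
#'                   data.frame(x = c(0, 50), y = c(1, 50)), threshold = 2)
#' c(m$tp, m$fp, m$fn)
#' @export
match_points <- function(pred, truth, threshold = 4,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  pred <- as_points(pred)
  truth <- as_points(truth)
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (np > 0L && nt > 0L) {
    d <- cross_dist(pred, truth)
    idx <- which(d <= threshold, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      cand <- data.frame(pred = idx[, 1L], truth = idx[, 2L],
                         distance = d[idx])
      cand <- cand[order(cand$distance, cand$pred, cand$truth), , drop = FALSE]
      pairs <- if (method == "greedy") {
        match_greedy(cand, np, nt)
      } else {
        match_optimal(cand, np, nt)
      }
    }
  }
  tp <- nrow(pairs); fp <- np - tp; fn <- nt - tp
  precision <- if (tp + fp == 0L) (if (fn == 0L) 1 else 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  jaccard <- if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = precision, recall = recall, jaccard = jaccard,
                 threshold = threshold, method = method),
            class = "match_result")
}

as_points <- function(p) {
  if (is.matrix(p)) p <- as.data.frame(p)
  if (nrow(p) == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  if (!all(c("x", "y") %in% names(p))) {
    names(p)[1:2] <- c("x", "y")
  }
  data.frame(x = as.numeric(p$x), y = as.numeric(p$y))
}

match_greedy <- function(cand, np, nt) {
  used_p <- logical(np); used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pi <- cand$pred[i]; ti <- cand$truth[i]
    if (!used_p[pi] && !used_t[ti]) {
      used_p[pi] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

# Maximum-cardinality bipartite matching (Kuhn's augmenting paths) on the
# threshold graph; among maximum matchings no particular distance optimality
# is claimed.
match_optimal <- function(cand, np, nt) {
  adj <- split(cand$truth, factor(cand$pred, levels = seq_len(np)))
  match_t <- integer(nt)  # 0 = free, else pred index
  aug <- function(p, seen_env) {
    for (t in adj[[p]]) {
      if (!seen_env$seen[t]) {
        seen_env$seen[t] <- TRUE
        if (match_t[t] == 0L || aug(match_t[t], seen_env)) {
          match_t[t] <<- p
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (p in seq_len(np)) {
    if (length(adj[[p]]) > 0L) {
      env <- new.env(); env$seen <- logical(nt)
      aug(p, env)
    }
  }
  matched <- which(match_t > 0L)
  if (length(matched) == 0L) return(cand[0, , drop = FALSE])
  out <- data.frame(pred = match_t[matched], truth = matched)
  # attach distances from the candidate table
  key <- paste(cand$pred, cand$truth)
  out$distance <- cand$distance[match(paste(out$pred, out$truth), key)]
  out[order(out$distance, out$pred), , drop = FALSE]
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Point matching (%s, radius %g px): TP %d, FP %d, FN %d | precision %.3f, recall %.3f, Jaccard %.3f\n",
              x$method, x$threshold, x$tp, x$fp, x$fn,
              x$precision, x$recall, x$jaccard))
  invisible(x)
}

#' Jaccard index between two point sets
#'
#' `tp / (tp + fp + fn)` from [match_points()]; the intersection-over-union
#' of two annotation sets under a correctness radius. Symmetric for points
#' in generic position.
#'
#' @inheritParams match_points
#' @param set_a,set_b Data frames with columns `x`, `y`.
#' @return A single value in `[0, 1]`.
#' @export
jaccard_between <- function(set_a, set_b, threshold = 4) {
  match_points(set_a, set_b, threshold)$jaccard
}

#' Nearest-neighbor distance statistics of a point set
#'
#' @param points Data frame with columns `x`, `y` (>= 2 rows).
#' @return List with `mean`, `median`, `min` of the per-point
#'   nearest-neighbor Euclidean distances, plus the vector `nnd`.
#' @export
nnd_stats <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 2L) {
    stop("nearest-neighbor statistics undefined for fewer than 2 points",
         call. = FALSE)
  }
  d <- nn_dist(points)
  list(mean = mean(d), median = stats::median(d), min = min(d), nnd = d)
}

#' Per-worker and per-spot performance of an annotation set
#'
#' Summarizes how a crowd covered a set of true spots: per worker the
#' click count and matched-click recall; per spot the fraction of workers
#' with at least one click within `threshold`; and aggregates including
#' the fraction of spots covered by at least half the workers.
#'
#' @param annos Annotation data frame (`worker_id`, `x`, `y`, ...).
#' @param truth Data frame of true spots with columns `x`, `y`.
#' @param threshold Correctness radius in pixels.
#' @return List with data frames `per_worker`
#'   (`worker_id, n_clicks, recall`), `per_spot`
#'   (`spot, worker_coverage`), and `summary` (mean clicks/worker, mean
#'   per-worker recall, fraction of spots covered by >= 50% of workers).
#' @export
worker_performance <- function(annos, truth, threshold = 4) {
  stopifnot(nrow(annos) >= 1L)
  workers <- unique(annos$worker_id)
  nt <- nrow(truth)
  cov <- matrix(FALSE, nrow = nt, ncol = length(workers))
  per_worker <- data.frame(worker_id = workers, n_clicks = 0L, recall = NA_real_,
                           stringsAsFactors = FALSE)
  for (j in seq_along(workers)) {
    wa <- annos[annos$worker_id == workers[j], , drop = FALSE]
    per_worker$n_clicks[j] <- nrow(wa)
    m <- match_points(wa, truth, threshold)
    per_worker$recall[j] <- m$recall
    if (nrow(m$pairs) > 0L) cov[m$pairs$truth, j] <- TRUE
  }
  worker_coverage <- rowMeans(cov)
  list(per_worker = per_worker,
       per_spot = data.frame(spot = seq_len(nt),
                             worker_coverage = worker_coverage),
       summary = list(mean_clicks_per_worker = mean(per_worker$n_clicks),
                      mean_worker_recall = mean(per_worker$recall),
                      frac_spots_majority_covered =
                        if (nt == 0L) NA_real_ else mean(worker_coverage >= 0.5)))
}

#' Annotation capacity in cells per image
#'
#' Given a per-image click ceiling (the number of spots one annotator is
#' willing to click in a single image) and an expected number of spots per
#' cell, returns how many cells' worth of spots one annotator can cover:
#' `click_ceiling / spots_per_cell`.
#'
#' @param click_ceiling Clicks per worker per image (empirically ~120).
#' @param spots_per_cell Expected spots per cell (> 0).
#' @return Cells per image (real).
#' @examples
#' annotation_capacity(120, 25)  # 4.8 cells per image
#' @export
annotation_capacity <- function(click_ceiling, spots_per_cell) {
  if (!is.numeric(spots_per_cell) || spots_per_cell <= 0) {
    stop("`spots_per_cell` must be positive", call. = FALSE)
  }
  click_ceiling / spots_per_cell
}
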