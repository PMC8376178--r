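# Dense affinity-propagation message passing (responsibilities /
# availabilities with damping). S is the similarity matrix with
# preferences on the diagonal. Returns exemplar-index labels per point and
# a convergence flag. Fully deterministic: no tie-breaking noise is added;
# ties resolve by lowest index.
affinity_propagation <- function(S, damping = 0.9, max_iter = 300L,
                                 convergence_iter = 30L) {
  n <- nrow(S)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L
  exemplars_prev <- integer(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    idx1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), idx1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), idx1)] <- S[cbind(seq_len(n), idx1)] - max2
    R <- damping * R + (1 - damping) * Rnew

    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    exemplars <- which(diag(A) + diag(R) > 0)
    if (length(exemplars) > 0L && identical(exemplars, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= convergence_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    exemplars_prev <- exemplars
  }
  exemplars <- which(diag(A) + diag(R) > 0)
  if (length(exemplars) == 0L) {
    return(list(labels = rep(1L, n), exemplars = 1L, converged = FALSE))
  }
  lab <- apply(S[, exemplars, drop = FALSE], 1L, which.max)
  lab[exemplars] <- seq_along(exemplars)
  list(labels = as.integer(lab), exemplars = exemplars, converged = converged)
}

#' Cluster redundant point annotations
#'
#' Groups a crowd's clicks into per-spot clusters by affinity propagation
#' on negative squared Euclidean distances, with the preference (the
#' diagonal of the similarity matrix) set to the median similarity over
#' all annotation pairs. To keep the message passing stable and fast at
#' crowd scale, annotations are first partitioned into spatial components
#' by single linkage at `component_radius`; affinity propagation then
#' runs within each component with the shared global preference. A
#' component whose message passing fails to converge falls back to a
#' single cluster per single-linkage group at `fallback_radius`, with a
#' warning.
#'
#' @param annos Annotation data frame (`worker_id`, `x`, `y`, ...), at
#'   least one row.
#' @param component_radius Single-linkage pre-partition radius, pixels.
#' @param preference Affinity-propagation preference; `NULL` (default)
#'   uses the median similarity (negative squared distance) over all
#'   annotation pairs.
#' @param damping,max_iter,convergence_iter Message-passing controls.
#' @param fallback_radius Single-linkage radius used when a component's
#'   message passing does not converge.
#' @return List of class `cluster_set`: `clusters` (data frame
#'   `cluster_id, x, y, n_annotations, n_unique_workers, multi_frac`),
#'   `assignment` (cluster index per annotation row), `annotations`, and
#'   `params` (the clustering settings actually used, for logging).
#' @export
cluster_annotations <- function(annos, component_radius = 5,
                                preference = NULL, damping = 0.9,
                                max_iter = 300L, convergence_iter = 30L,
                                fallback_radius = component_radius) {
  if (is.null(annos) || nrow(annos) == 0L) {
    stop("cannot cluster an empty annotation set", call. = FALSE)
  }
  X <- cbind(annos$x, annos$y)
  n <- nrow(X)
  if (is.null(preference)) {
    preference <- if (n >= 2L) {
      -stats::median(stats::dist(X)^2)
    } else {
      -1
    }
  }
  assignment <- integer(n)
  nxt <- 0L
  comp <- single_linkage_groups(X, component_radius)
  for (cg in unique(comp)) {
    idx <- which(comp == cg)
    if (length(idx) <= 2L) {
      nxt <- nxt + 1L
      assignment[idx] <- nxt
      next
    }
    sub <- X[idx, , drop = FALSE]
    D2 <- as.matrix(stats::dist(sub))^2
    S <- -D2
    diag(S) <- preference
    ap <- affinity_propagation(S, damping = damping, max_iter = max_iter,
                               convergence_iter = convergence_iter)
    labs <- ap$labels
    if (!ap$converged) {
      warning(sprintf(
        "affinity propagation did not converge for a component of %d annotations; falling back to single-linkage clustering at radius %g",
        length(idx), fallback_radius), call. = FALSE)
      labs <- single_linkage_groups(sub, fallback_radius)
    }
    for (u in unique(labs)) {
      nxt <- nxt + 1L
      assignment[idx[labs == u]] <- nxt
    }
  }
  clusters <- cluster_table(annos, assignment)
  structure(list(clusters = clusters, assignment = assignment,
                 annotations = annos,
                 params = list(component_radius = component_radius,
                               preference = preference, damping = damping,
                               max_iter = max_iter,
                               convergence_iter = convergence_iter)),
            class = "cluster_set")
}

# Summarize clusters: centroid, sizes, and the fraction of unique
# contributing workers who contributed more than one click.
cluster_table <- function(annos, assignment) {
  ids <- sort(unique(assignment))
  do.call(rbind, lapply(ids, function(k) {
    ix <- which(assignment == k)
    wk <- table(annos$worker_id[ix])
    data.frame(cluster_id = sprintf("k%04d", k),
               x = mean(annos$x[ix]), y = mean(annos$y[ix]),
               n_annotations = length(ix),
               n_unique_workers = length(wk),
               multi_frac = sum(wk >= 2L) / length(wk),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Annotation clustering: %d annotations -> %d clusters (preference %.4g, damping %.2g)\n",
              nrow(x$annotations), nrow(x$clusters), x$params$preference,
              x$params$damping))
  invisible(x)
}

#' Cluster-size thresholding
#'
#' First QC rule: clusters supported by few annotators tend to be false
#' positives. One-dimensional k-means with k = 2 (deterministic
#' initialization at the minimum and maximum observed value, Lloyd
#' iterations to convergence) splits the cluster-size distribution; the
#' threshold is the midpoint of the two final centers and clusters below
#' it are removed. The removal is monotone: every removed cluster is no
#' larger than any kept cluster.
#'
#' The statistic defaults to the number of unique contributing workers,
#' which is robust when clumped clusters inflate raw click counts; raw
#' annotation counts are available via `stat = "annotations"`.
#'
#' @param clusters Cluster data frame (from a `cluster_set`) or a
#'   `cluster_set`.
#' @param stat `"workers"` (unique contributing workers, default) or
#'   `"annotations"` (raw click count).
#' @return List with `kept` and `removed` (logical index aligned with the
#'   cluster rows), `threshold`, `stat`. With fewer than two distinct
#'   sizes everything is kept and the threshold is the minimum size.
#' @export
size_threshold <- function(clusters, stat = c("workers", "annotations")) {
  stat <- match.arg(stat)
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  v <- if (stat == "workers") cl$n_unique_workers else cl$n_annotations
  if (length(v) < 2L || length(unique(v)) < 2L) {
    return(list(kept = rep(TRUE, length(v)), removed = rep(FALSE, length(v)),
                threshold = if (length(v)) min(v) else NA_real_, stat = stat))
  }
  km <- stats::kmeans(matrix(as.numeric(v), ncol = 1L),
                      centers = matrix(c(min(v), max(v)), ncol = 1L),
                      iter.max = 100L, algorithm = "Lloyd")
  threshold <- mean(range(km$centers))
  kept <- v >= threshold
  list(kept = kept, removed = !kept, threshold = threshold, stat = stat)
}

#' Detect clumpy clusters from the multi-click fraction
#'
#' Second QC rule: when adjacent spots are lumped into one cluster, an
#' elevated fraction of its unique workers contribute more than one click
#' (`multi_frac`). The fractions are histogrammed over `[0, 1]`; scanning
#' from just past the main mode toward 1, the threshold is placed at the
#' left edge of the bin with the largest positive count increase (the
#' point of steepest increase between mode and tail). Clusters at or
#' above the threshold are flagged for declumping. With no increase
#' beyond the mode, nothing is flagged.
#'
#' @param clusters Cluster data frame with a `multi_frac` column (or a
#'   `cluster_set`, or a numeric vector of fractions).
#' @param n_bins Number of histogram bins over `[0, 1]` (>= 4).
#' @return List with `flagged` (logical), `threshold_frac` (`NA` when
#'   nothing is flagged), and `counts` (the histogram).
#' @export
detect_clumpy <- function(clusters, n_bins = 10L) {
  stopifnot(n_bins >= 4L)
  mf <- if (is.numeric(clusters)) clusters else {
    cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
    cl$multi_frac
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(mf, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mode_bin <- which.max(counts)
  best_bin <- NA_integer_; best_inc <- 0
  b <- mode_bin + 1L
  while (b <= n_bins) {
    inc <- counts[b] - counts[b - 1L]
    if (inc > best_inc) { best_inc <- inc; best_bin <- b }
    b <- b + 1L
  }
  if (is.na(best_bin)) {
    return(list(flagged = rep(FALSE, length(mf)), threshold_frac = NA_real_,
                counts = counts))
  }
  thr <- breaks[best_bin]
  list(flagged = mf >= thr & mf > 0, threshold_frac = thr, counts = counts)
}

# Deterministic farthest-point seeding for k-means (k-means++-style
# without randomness): first seed is the point farthest from the member
# centroid, each further seed the point farthest from the seeds chosen.
farthest_point_seeds <- function(X, k) {
  ctr <- colMeans(X)
  d0 <- (X[, 1L] - ctr[1L])^2 + (X[, 2L] - ctr[2L])^2
  seeds <- which.max(d0)
  while (length(seeds) < k) {
    dmin <- apply(cross_dist(X, X[seeds, , drop = FALSE]), 1L, min)
    dmin[seeds] <- -Inf
    seeds <- c(seeds, which.max(dmin))
  }
  X[seeds, , drop = FALSE]
}

#' Split a clumpy cluster by 2-D k-means
#'
#' Partitions a flagged cluster's member clicks into `k` sub-clusters
#' (default 2, the adjacent-pair case) with deterministic farthest-point
#' seeding and Lloyd iterations. Children carry `origin = "declumped"`
#' and together contain exactly the parent's members.
#'
#' @param members Data frame of the cluster's member annotations
#'   (`worker_id`, `x`, `y`, ...).
#' @param k Number of children (>= 2).
#' @return Data frame with one row per child:
#'   `x, y, n_annotations, n_unique_workers, origin`, plus a `member`
#'   list-column of member row indices. If the cluster has fewer members
#'   than `k` it is returned unsplit with a warning.
#' @export
declump <- function(members, k = 2L) {
  stopifnot(k >= 2L)
  X <- cbind(members$x, members$y)
  if (nrow(X) < k) {
    warning("cluster has fewer members than k; returned unchanged", call. = FALSE)
    out <- data.frame(x = mean(members$x), y = mean(members$y),
                      n_annotations = nrow(members),
                      n_unique_workers = length(unique(members$worker_id)),
                      origin = "retained", stringsAsFactors = FALSE)
    out$member <- list(seq_len(nrow(members)))
    return(out)
  }
  km <- stats::kmeans(X, centers = farthest_point_seeds(X, k),
                      iter.max = 50L, algorithm = "Lloyd")
  out <- do.call(rbind, lapply(seq_len(k), function(j) {
    ix <- which(km$cluster == j)
    d <- data.frame(x = mean(members$x[ix]), y = mean(members$y[ix]),
                    n_annotations = length(ix),
                    n_unique_workers = length(unique(members$worker_id[ix])),
                    origin = "declumped", stringsAsFactors = FALSE)
    d$member <- list(ix)
    d
  }))
  out
}

#' Run the full annotation QC pipeline
#'
#' Fixed stage order: cluster the annotations, remove under-supported
#' clusters (size thresholding), flag clumpy clusters among the survivors
#' (multi-click fraction), and declump the flagged clusters. The
#' consensus is the centroids of unflagged kept clusters plus the
#' declumped child centroids. Declumping after false-positive removal
#' recovers recall lost to merged adjacent spots without re-admitting the
#' removed noise clusters.
#'
#' @param annos Annotation data frame (`worker_id`, `x`, `y`, ...).
#' @param component_radius,preference,damping Passed to
#'   [cluster_annotations()].
#' @param size_stat Passed to [size_threshold()] as `stat`.
#' @param n_bins Passed to [detect_clumpy()].
#' @param declump_k Children per declumped cluster.
#' @return List of class `qc_result`: `consensus` (data frame
#'   `x, y, n_support, origin`), `clusters` (the `cluster_set`), `size`
#'   and `clump` stage results, and `log` (per-stage counts and
#'   thresholds).
#' @examples
#' sim <- simulate_spot_image(synth_config(n_spots = 12, seed = 3),
#'                            width = 160, height = 160)
#' crowd <- simulate_crowd(sim$truth, 160, 160, n_workers = 10, seed = 3)
#' qc <- run_qc(crowd)
#' nrow(qc$consensus)
#' @export
run_qc <- function(annos, component_radius = 5, preference = NULL,
                   damping = 0.9, size_stat = c("workers", "annotations"),
                   n_bins = 10L, declump_k = 2L) {
  size_stat <- match.arg(size_stat)
  cs <- cluster_annotations(annos, component_radius = component_radius,
                            preference = preference, damping = damping)
  st <- size_threshold(cs, stat = size_stat)
  kept_idx <- which(st$kept)
  kept_cl <- cs$clusters[kept_idx, , drop = FALSE]
  dc <- detect_clumpy(kept_cl, n_bins = n_bins)
  consensus <- list()
  for (j in seq_along(kept_idx)) {
    ix <- which(cs$assignment == kept_idx[j])
    if (dc$flagged[j] && length(ix) >= declump_k) {
      ch <- declump(cs$annotations[ix, , drop = FALSE], k = declump_k)
      consensus[[length(consensus) + 1L]] <-
        data.frame(x = ch$x, y = ch$y, n_support = ch$n_annotations,
                   origin = "declumped", stringsAsFactors = FALSE)
    } else {
      consensus[[length(consensus) + 1L]] <-
        data.frame(x = kept_cl$x[j], y = kept_cl$y[j],
                   n_support = kept_cl$n_annotations[j],
                   origin = "retained", stringsAsFactors = FALSE)
    }
  }
  consensus <- if (length(consensus)) do.call(rbind, consensus) else {
    data.frame(x = numeric(0), y = numeric(0), n_support = integer(0),
               origin = character(0))
  }
  structure(list(consensus = consensus, clusters = cs, size = st, clump = dc,
                 log = list(n_annotations = nrow(annos),
                            n_clusters = nrow(cs$clusters),
                            size_stat = size_stat,
                            size_threshold = st$threshold,
                            n_removed = sum(st$removed),
                            clump_threshold = dc$threshold_frac,
                            n_flagged = sum(dc$flagged),
                            n_consensus = nrow(consensus))),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  lg <- x$log
  cat(sprintf("Annotation QC: %d annotations -> %d clusters; size threshold %.3g (%s) removed %d; %d clumpy declumped; %d consensus points\n",
              lg$n_annotations, lg$n_clusters, lg$size_threshold, lg$size_stat,
              lg$n_removed, lg$n_flagged, lg$n_consensus))
  invisible(x)
}

#' Sensitivity and specificity of a QC decision
#'
#' Against known truth (synthetic runs): a cluster is *correct* when its
#' centroid lies within `radius` of an unclaimed true spot (greedy
#' nearest assignment, one spot per cluster). Sensitivity is the fraction
#' of incorrect clusters that the decision removed; specificity the
#' fraction of correct clusters it kept. Both report 1 when their
#' denominator is empty (nothing incorrect to remove / nothing correct to
#' keep).
#'
#' @param clusters Cluster data frame with columns `x`, `y`.
#' @param removed Logical vector: was each cluster removed by QC?
#' @param truth Data frame of true spots (`x`, `y`).
#' @param radius Correctness radius in pixels.
#' @return List with `sensitivity`, `specificity`, and the logical
#'   `correct` vector.
#' @export
qc_confusion <- function(clusters, removed, truth, radius = 4) {
  cl <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  stopifnot(length(removed) == nrow(cl))
  m <- match_points(cl[, c("x", "y")], truth, threshold = radius)
  correct <- logical(nrow(cl))
  if (nrow(m$pairs) > 0L) correct[m$pairs$pred] <- TRUE
  n_incorrect <- sum(!correct)
  n_correct <- sum(correct)
  list(sensitivity = if (n_incorrect == 0L) 1 else sum(!correct & removed) / n_incorrect,
       specificity = if (n_correct == 0L) 1 else sum(correct & !removed) / n_correct,
       correct = correct)
}
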