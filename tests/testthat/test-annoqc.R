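jittered_groups <- function(centers, n_each = 10L, jitter = 0.5, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    data.frame(worker_id = sprintf("w%02d", seq_len(n_each)),
               x = rnorm(n_each, centers$x[g], jitter),
               y = rnorm(n_each, centers$y[g], jitter))
  }))
}

test_that("clustering recovers well-separated click groups", {
  one <- data.frame(worker_id = "w01", x = 5, y = 7)
  cs1 <- cluster_annotations(one)
  expect_equal(nrow(cs1$clusters), 1L)
  expect_equal(cs1$clusters$x, 5)
  expect_equal(cs1$clusters$y, 7)

  centers <- data.frame(x = c(20, 120, 220), y = c(20, 120, 40))
  annos <- jittered_groups(centers, seed = 3)
  cs <- cluster_annotations(annos)
  expect_equal(nrow(cs$clusters), 3L)
  for (g in 1:3) {
    gm <- colMeans(annos[((g - 1) * 10 + 1):(g * 10), c("x", "y")])
    d <- sqrt((cs$clusters$x - gm[1])^2 + (cs$clusters$y - gm[2])^2)
    expect_lt(min(d), 1)
  }
  # partition: cluster sizes sum to the annotation count
  expect_equal(sum(cs$clusters$n_annotations), nrow(annos))
  expect_equal(length(cs$assignment), nrow(annos))

  expect_error(cluster_annotations(data.frame()), "empty")
})

test_that("cluster statistics count unique and multi-clicking workers", {
  annos <- data.frame(worker_id = c("a", "a", "b", "c"),
                      x = c(10, 10.5, 10.2, 9.8), y = rep(10, 4))
  # explicit preference at the typical inter-spot scale: one tight blob of
  # clicks stays one cluster
  cs <- cluster_annotations(annos, preference = -100)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$n_annotations, 4L)
  expect_equal(cs$clusters$n_unique_workers, 3L)
  expect_equal(cs$clusters$multi_frac, 1 / 3)
})

test_that("size thresholding reproduces the brute-force 1-D split", {
  mk <- function(sizes) {
    data.frame(cluster_id = sprintf("k%d", seq_along(sizes)),
               x = seq_along(sizes) * 100, y = 0, n_annotations = sizes,
               n_unique_workers = sizes, multi_frac = 0)
  }
  sizes <- c(25, 24, 23, 2, 1)
  st <- size_threshold(mk(sizes), stat = "annotations")
  expect_equal(which(st$removed), c(4L, 5L))
  # oracle: optimal 2-means split over all split points
  expect_equal(sizes >= bf_two_means_split(sizes), st$kept)
  # monotone: smallest kept is at least the largest removed
  expect_gte(min(sizes[st$kept]), max(sizes[st$removed]))

  st_eq <- size_threshold(mk(c(5, 5, 5)))
  expect_true(all(st_eq$kept))

  st_one <- size_threshold(mk(7))
  expect_true(st_one$kept)
})

test_that("clump detection places the threshold at the steepest increase", {
  none <- detect_clumpy(rep(0, 20))
  expect_false(any(none$flagged))

  fr <- c(rep(0, 18), 0.05, 0.5, 0.55, 0.6)
  dc <- detect_clumpy(fr, n_bins = 10L)
  expect_equal(dc$threshold_frac, 0.5)
  expect_equal(which(dc$flagged), 20:22)  # exactly the three >= 0.5

  declining <- c(rep(0.05, 10), rep(0.15, 6), rep(0.25, 3), 0.35)
  dd <- detect_clumpy(declining, n_bins = 10L)
  expect_false(any(dd$flagged))
})

test_that("declumping splits a two-spot cluster and conserves members", {
  set.seed(5)
  members <- data.frame(
    worker_id = sprintf("w%02d", rep(1:10, 2)),
    x = c(rnorm(10, 0, 0.3), rnorm(10, 6, 0.3)),
    y = rnorm(20, 0, 0.3))
  ch <- declump(members, k = 2L)
  expect_equal(nrow(ch), 2L)
  expect_equal(sum(ch$n_annotations), 20L)
  cx <- sort(ch$x)
  expect_lt(abs(cx[1] - 0), 1)
  expect_lt(abs(cx[2] - 6), 1)
  expect_true(all(ch$origin == "declumped"))

  two <- data.frame(worker_id = c("a", "b"), x = c(0, 4), y = c(0, 0))
  ch2 <- declump(two, k = 2L)
  expect_equal(sort(ch2$x), c(0, 4))

  expect_warning(declump(two[1, ], k = 2L), "fewer members")
})

test_that("full QC on a clean crowd is a fixed point", {
  sim <- simulate_spot_image(
    synth_config(n_spots = 10L, min_nnd = 40, seed = 2), 256, 256)
  m <- worker_model(p_detect_midpoint = -Inf, click_jitter_sigma = 0,
                    fp_rate = 0, merge_radius_frac = 0)
  crowd <- simulate_crowd(sim$truth, 256, 256, m, n_workers = 25, seed = 2)
  qc <- suppressWarnings(run_qc(crowd))
  expect_equal(nrow(qc$consensus), 10L)
  mm <- match_points(qc$consensus, sim$truth, threshold = 0.5)
  expect_equal(mm$tp, 10L)
})

test_that("QC removes sparse false-positive clusters", {
  sim <- simulate_spot_image(
    synth_config(n_spots = 20L, min_nnd = 20, seed = 6), 256, 256)
  crowd <- simulate_crowd(sim$truth, 256, 256, n_workers = 25, seed = 6)
  qc <- run_qc(crowd)
  m <- match_points(qc$consensus, sim$truth)
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.9)
  # every annotation is attributable to exactly one cluster
  expect_equal(sum(qc$clusters$clusters$n_annotations), nrow(crowd))
  # monotone size rule among the QC decisions
  v <- qc$clusters$clusters$n_unique_workers
  if (any(qc$size$removed)) {
    expect_gte(min(v[qc$size$kept]), max(v[qc$size$removed]))
  }
})

test_that("a constructed clump is declumped onto its two source spots", {
  # 10 isolated spots plus one close pair annotated as a clump: most
  # workers click once near the pair midpoint, a burst of workers click
  # both spots
  set.seed(9)
  iso <- data.frame(x = seq(20, 200, 20), y = 200)
  pairA <- c(100, 40); pairB <- c(108, 40)
  rows <- list()
  for (w in 1:20) {
    wid <- sprintf("w%02d", w)
    for (i in seq_len(nrow(iso))) {
      rows[[length(rows) + 1L]] <- data.frame(
        worker_id = wid, x = iso$x[i] + rnorm(1, 0, 0.5),
        y = iso$y[i] + rnorm(1, 0, 0.5))
    }
    if (w <= 8) {
      rows[[length(rows) + 1L]] <- data.frame(
        worker_id = wid, x = (pairA[1] + pairB[1]) / 2 + rnorm(1, 0, 0.5),
        y = 40 + rnorm(1, 0, 0.5))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        worker_id = wid, x = pairA[1] + rnorm(1, 0, 0.5),
        y = 40 + rnorm(1, 0, 0.5))
      rows[[length(rows) + 1L]] <- data.frame(
        worker_id = wid, x = pairB[1] + rnorm(1, 0, 0.5),
        y = 40 + rnorm(1, 0, 0.5))
    }
  }
  annos <- do.call(rbind, rows)
  qc <- run_qc(annos)
  expect_equal(sum(qc$consensus$origin == "declumped"), 2L)
  truth <- rbind(iso, data.frame(x = c(pairA[1], pairB[1]), y = 40))
  m <- match_points(qc$consensus, truth, threshold = 4)
  expect_equal(m$tp, 12L)
})

test_that("QC confusion counts follow their construction", {
  truth <- data.frame(x = c(0, 50, 100), y = 0)
  clusters <- data.frame(x = c(0.5, 50.2, 100.1, 300, 400),
                         y = c(0, 0, 0, 0, 0))
  conf <- qc_confusion(clusters, removed = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                       truth, radius = 4)
  expect_equal(conf$sensitivity, 1)
  expect_equal(conf$specificity, 1)

  conf2 <- qc_confusion(clusters[1:4, ],
                        removed = c(TRUE, FALSE, FALSE, FALSE), truth,
                        radius = 4)
  expect_equal(conf2$specificity, 2 / 3)
  expect_equal(conf2$sensitivity, 0)

  conf3 <- qc_confusion(clusters[1:3, ], removed = rep(FALSE, 3), truth,
                        radius = 4)
  expect_equal(conf3$sensitivity, 1)  # nothing incorrect: convention
  expect_equal(conf3$specificity, 1)
})

test_that("QC is deterministic for fixed inputs", {
  sc <- make_sim_crowd(31, n_spots = 40L, width = 256L, height = 256L)
  q1 <- run_qc(sc$crowd)
  q2 <- run_qc(sc$crowd)
  expect_identical(q1$consensus, q2$consensus)
})
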