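test_that("preprocessing removes flat structure and localizes spots", {
  expect_lt(max(preprocess_stack(matrix(42, 64, 64), 3)), 1e-8)

  # spot in plane 1 only: projected output peaks at the spot
  bg <- matrix(10, 64, 64)
  cfg <- synth_config(n_spots = 1L, snr_mean = 30, snr_spread = 0,
                      sigma = 1.5, seed = 1L)
  plane1 <- render_spots(bg, data.frame(x = 40, y = 22), cfg)$image
  out <- preprocess_stack(list(plane1, bg), highpass_sigma = 4.5)
  pk <- which(out == max(out), arr.ind = TRUE)[1, ]
  expect_lte(abs(pk["col"] - 1 - 40), 1)
  expect_lte(abs(pk["row"] - 1 - 22), 1)
  expect_gte(min(out), 0)

  # max projection of identical planes equals the single-plane result
  single <- preprocess_stack(plane1, 4.5)
  triple <- preprocess_stack(list(plane1, plane1, plane1), 4.5)
  expect_equal(single, triple)
})

test_that("LoG detection finds an isolated Gaussian at the right scale", {
  expect_equal(nrow(log_detect(matrix(5, 64, 64), 1, 3, 5, 0)), 0L)

  bg <- matrix(10, 96, 96)
  cfg <- synth_config(n_spots = 1L, snr_mean = 100, snr_spread = 0,
                      sigma = 2, seed = 1L)
  img <- render_spots(bg, data.frame(x = 50, y = 44), cfg)$image
  det <- log_detect(img, 1, 4, n_scales = 9L, threshold = 1)
  expect_equal(nrow(det), 1L)
  expect_lte(abs(det$x - 50), 1)
  expect_lte(abs(det$y - 44), 1)
  grid_step <- exp(log(4 / 1) / 8)
  expect_lte(abs(log(det$sigma / 2)), log(grid_step) + 1e-9)
})

test_that("raising the LoG threshold only removes detections", {
  sim <- simulate_spot_image(synth_config(n_spots = 25L, seed = 5), 200, 200)
  d1 <- log_detect(sim$image, 1, 3, 8, threshold = 5)
  d2 <- log_detect(sim$image, 1, 3, 8, threshold = 30)
  key <- function(d) paste(d$x, d$y, signif(d$sigma, 10))
  expect_true(all(key(d2) %in% key(d1)))
  expect_lte(nrow(d2), nrow(d1))
})

test_that("LoG detection equals the dense-scan oracle on small images", {
  bg <- generate_background(64, 64, 20, 2, seed = 31)
  cfg <- synth_config(n_spots = 3L, snr_mean = 40, snr_spread = 0,
                      sigma = 1.5, min_nnd = 15, seed = 31)
  loc <- sample_spot_locations(cfg, 64, 64)
  img <- render_spots(bg, loc, cfg)$image
  got <- log_detect(img, 1, 2.5, n_scales = 4L, threshold = 10)
  want <- oracle_log_detect(img, 1, 2.5, 4L, 10)
  expect_equal(nrow(got), nrow(want))
  key <- function(d) sort(paste(d$x, d$y, signif(d$sigma, 8)))
  expect_equal(key(got), key(want))
})

test_that("crowded-region boxes follow single-linkage geometry", {
  gl <- guidelines()
  far <- data.frame(x = c(10, 200, 400), y = c(10, 200, 400))
  expect_equal(nrow(find_crowded_regions(far, gl, 512, 512)), 0L)

  pair <- data.frame(x = c(100, 105), y = c(100, 100))
  b <- find_crowded_regions(pair, gl, 512, 512)
  expect_equal(nrow(b), 1L)
  expect_lte(b$x0, 100 - 30)
  expect_gte(b$x1, 105 + 30)

  two_pairs <- data.frame(x = c(50, 55, 450, 455), y = c(50, 50, 450, 450))
  b2 <- find_crowded_regions(two_pairs, gl, 512, 512)
  expect_equal(nrow(b2), 2L)
  expect_lt(b2$x1[1], b2$x0[2])
})

test_that("subdivision splits crowded corners and respects the depth cap", {
  img_sparse <- matrix(1, 256, 256)
  sparse <- data.frame(x = c(30, 130, 230), y = c(30, 130, 230))
  out <- recursive_subdivide(img_sparse, sparse, guidelines(),
                             display_width = 256)
  expect_equal(length(out), 1L)
  expect_equal(out[[1]]$spec$depth, 0L)
  expect_equal(out[[1]]$spec$flag, "ok")

  # 300 spots packed into one 100x100 corner of a 512x512 image
  set.seed(17)
  packed <- data.frame(x = runif(300, 5, 100), y = runif(300, 5, 100))
  img <- matrix(1, 512, 512)
  gl <- guidelines()
  out2 <- recursive_subdivide(img, packed, gl, display_width = 450)
  expect_gt(length(out2), 1L)
  man <- crop_manifest(out2)
  expect_lte(max(man$depth), gl$max_depth)
  expect_lte(nrow(man), 4^gl$max_depth + 1)
  # every non-saturated leaf satisfies both guideline criteria
  for (cr in out2[-1]) {
    sp <- cr$spec
    if (sp$flag == "saturated") next
    inside <- packed$x >= sp$x0 & packed$x < sp$x0 + sp$width &
      packed$y >= sp$y0 & packed$y < sp$y0 + sp$height
    s <- packed[inside, ]
    expect_lte(nrow(s), gl$max_spots_per_crop)
    if (nrow(s) >= 2) {
      d <- as.matrix(dist(s)); diag(d) <- Inf
      expect_gte(min(d) * sp$scale, gl$min_display_nnd_frac * 450)
    }
  }

  out3 <- recursive_subdivide(img, packed, guidelines(max_depth = 0),
                              display_width = 450)
  expect_equal(length(out3), 1L)
  expect_equal(out3[[1]]$spec$flag, "saturated")
})

test_that("crop coordinate mapping is exact arithmetic", {
  spec <- list(crop_id = "c0.1", x0 = 100L, y0 = 200L, width = 50L,
               height = 50L, scale = 4)
  p <- map_to_parent(spec, data.frame(x = 40, y = 80))
  expect_equal(p$x, 110)
  expect_equal(p$y, 220)

  pts <- data.frame(x = runif(20, 100, 149), y = runif(20, 200, 249))
  disp <- map_to_crop(spec, pts)
  back <- map_to_parent(spec, disp)
  expect_equal(back$x, pts$x, tolerance = 1e-12)
  expect_equal(back$y, pts$y, tolerance = 1e-12)

  ident <- list(crop_id = "c0", x0 = 0L, y0 = 0L, width = 500L,
                height = 500L, scale = 1)
  q <- data.frame(x = c(3.5, 7), y = c(1, 499))
  expect_equal(map_to_parent(ident, q), q, ignore_attr = TRUE)

  expect_error(map_to_parent(spec, data.frame(x = 999, y = 0)), "boundary")
})

test_that("reassembly dedups overlap reports and keeps distinct spots", {
  specs <- list(list(crop_id = "a", x0 = 0L, y0 = 0L, width = 100L,
                     height = 100L, scale = 1),
                list(crop_id = "b", x0 = 50L, y0 = 0L, width = 100L,
                     height = 100L, scale = 1))
  single <- reassemble(list(a = data.frame(x = c(10, 60), y = c(10, 60))),
                       specs, dedup_radius = 4)
  expect_equal(nrow(single), 2L)

  # same spot seen by both crops 1 px apart in the parent frame
  both <- reassemble(list(a = data.frame(x = 60, y = 40),
                          b = data.frame(x = 10.5, y = 40.5)),
                     specs, dedup_radius = 4)
  expect_equal(nrow(both), 1L)
  expect_equal(both$x, (60 + 60.5) / 2)
  expect_equal(both$n_sources, 2L)

  apart <- reassemble(list(a = data.frame(x = c(10, 60), y = c(50, 50))),
                      specs, dedup_radius = 4)
  expect_equal(nrow(apart), 2L)

  expect_error(reassemble(list(zzz = data.frame(x = 1, y = 1)), specs),
               "unknown crop_id")
})

test_that("subdivide + map + reassemble recovers truth without duplicates", {
  for (seed in 1:5) {
    sim <- simulate_spot_image(synth_config(n_spots = 80L, seed = seed),
                               256, 256)
    crops <- recursive_subdivide(sim$image, sim$truth, guidelines(),
                                 display_width = 450)
    pts <- lapply(crops, function(cr) map_to_crop(cr$spec, sim$truth))
    names(pts) <- vapply(crops, function(cr) cr$spec$crop_id, character(1))
    rec <- reassemble(pts, crops, dedup_radius = 2)
    expect_equal(nrow(rec), nrow(sim$truth))
    m <- match_points(rec, sim$truth, threshold = 2)
    expect_equal(m$tp, nrow(sim$truth))
  }
})
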