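#' Image-preparation guidelines
#'
#' Thresholds describing when an image is easy for annotators: spot SNR of
#' at least `min_snr`, mean nearest-neighbor spot distance between
#' `target_nnd_lo` and `target_nnd_hi` pixels, and—after upscaling for
#' display—no spot pair closer than `min_display_nnd_frac` of the
#' displayed width (annotation markers obscure closer neighbors). Crops
#' are also capped at `max_spots_per_crop` spots so one worker can finish
#' a crop within the per-image click budget.
#'
#' @param min_snr Minimum spot SNR for reliable annotation.
#' @param target_nnd_lo,target_nnd_hi Target nearest-neighbor distance
#'   band, pixels.
#' @param min_display_nnd_frac Minimum discernible NND as a fraction of
#'   displayed image width.
#' @param max_spots_per_crop Maximum spots per displayed crop.
#' @param max_depth Maximum subdivision recursion depth.
#' @return List of class `guidelines`.
#' @export
guidelines <- function(min_snr = 10, target_nnd_lo = 12, target_nnd_hi = 15,
                       min_display_nnd_frac = 0.04, max_spots_per_crop = 100L,
                       max_depth = 4L) {
  stopifnot(target_nnd_lo <= target_nnd_hi, min_display_nnd_frac > 0,
            min_display_nnd_frac < 1, max_spots_per_crop >= 1, max_depth >= 0)
  structure(list(min_snr = min_snr, target_nnd_lo = target_nnd_lo,
                 target_nnd_hi = target_nnd_hi,
                 min_display_nnd_frac = min_display_nnd_frac,
                 max_spots_per_crop = as.integer(max_spots_per_crop),
                 max_depth = as.integer(max_depth)),
            class = "guidelines")
}

#' Pre-process an image stack for spot detection
#'
#' Per z-plane: subtract a Gaussian blur (high-pass), apply a Laplacian
#' filter, rectify negative values to zero; then take the pixel-wise
#' maximum intensity projection across planes. The Laplacian is applied
#' with the sign convention that bright blobs give positive responses, so
#' rectification keeps spots and discards troughs. Filtering precedes
#' projection so plane-specific noise is suppressed before planes are
#' combined.
#'
#' @param stack A single matrix or a list of same-sized matrices
#'   (z-planes).
#' @param highpass_sigma High-pass Gaussian sigma in pixels (> 0); a rule
#'   of thumb is 3x the expected spot sigma.
#' @return Non-negative matrix of the same dimensions as one plane.
#' @export
preprocess_stack <- function(stack, highpass_sigma = 4.5) {
  if (is.matrix(stack)) stack <- list(stack)
  if (!is.list(stack) || length(stack) == 0L) {
    stop("`stack` must be a matrix or non-empty list of matrices", call. = FALSE)
  }
  stopifnot(highpass_sigma > 0)
  dims <- dim(stack[[1L]])
  filtered <- lapply(stack, function(p) {
    assert_image(p, "plane")
    if (!identical(dim(p), dims)) stop("all planes must share dimensions", call. = FALSE)
    hp <- p - gaussian_blur(p, highpass_sigma)
    pmax(laplacian_filter(hp), 0)
  })
  Reduce(pmax, filtered)
}

# Scale-normalized LoG response stack over a geometric sigma grid; bright
# blobs give positive peaks at their matching scale.
log_response_stack <- function(img, sigmas) {
  lapply(sigmas, function(s) s^2 * laplacian_filter(gaussian_blur(img, s)))
}

# TRUE where a matrix value is >= all 8 in-plane neighbors.
is_local_max_2d <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  res <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    res <- res & (m >= p[(2:(h + 1L)) + di, (2:(w + 1L)) + dj])
  }
  res
}

max3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  res <- matrix(-Inf, h, w)
  for (di in -1:1) for (dj in -1:1) {
    res <- pmax(res, p[(2:(h + 1L)) + di, (2:(w + 1L)) + dj])
  }
  res
}

#' Laplacian-of-Gaussian blob detection
#'
#' Multi-scale LoG detector: scale-normalized responses
#' `sigma^2 * Laplacian(Gaussian(img, sigma))` over a geometric sigma
#' grid; candidate spots are local maxima in (x, y, scale) above
#' `threshold`; overlapping detections (center distance below
#' `sqrt(2)` times the larger sigma) are pruned keeping the stronger.
#'
#' @param img Numeric matrix.
#' @param sigma_min,sigma_max Sigma grid bounds in pixels
#'   (`0 < sigma_min <= sigma_max`).
#' @param n_scales Number of geometric grid points (>= 1).
#' @param threshold Minimum normalized response (>= 0).
#' @return Data frame `x, y, sigma, response`, strongest first;
#'   coordinates 0-based pixel centers.
#' @export
log_detect <- function(img, sigma_min, sigma_max, n_scales = 10L,
                       threshold = 0) {
  assert_image(img)
  if (!(sigma_min > 0) || sigma_min > sigma_max) {
    stop("need 0 < sigma_min <= sigma_max", call. = FALSE)
  }
  stopifnot(n_scales >= 1, threshold >= 0)
  sigmas <- if (n_scales == 1L) sigma_min else {
    exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales))
  }
  resp <- log_response_stack(img, sigmas)
  # floor below FFT round-off so structureless images yield no responses
  eps <- 1e-8 * max(abs(img), 1)
  out <- list()
  for (s in seq_along(sigmas)) {
    cand <- is_local_max_2d(resp[[s]]) & resp[[s]] > max(threshold, eps)
    if (s > 1L) cand <- cand & (resp[[s]] >= max3x3(resp[[s - 1L]]))
    if (s < length(sigmas)) cand <- cand & (resp[[s]] >= max3x3(resp[[s + 1L]]))
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        x = idx[, 2L] - 1, y = idx[, 1L] - 1, sigma = sigmas[s],
        response = resp[[s]][idx])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      response = numeric(0)))
  }
  det <- do.call(rbind, out)
  det <- det[order(-det$response, det$x, det$y), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    ki <- which(keep)
    if (length(ki) == 0L) { keep[i] <- TRUE; next }
    d <- sqrt((det$x[ki] - det$x[i])^2 + (det$y[ki] - det$y[i])^2)
    lim <- sqrt(2) * pmax(det$sigma[ki], det$sigma[i])
    keep[i] <- all(d >= lim)
  }
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Find crowded spot regions
#'
#' Spots whose nearest-neighbor distance is below `target_nnd_hi` are
#' crowded; crowded spots are grouped by single linkage at that radius and
#' each group yields its axis-aligned bounding box, padded by
#' `2 * target_nnd_hi` and clipped to the image.
#'
#' @param spots Data frame with columns `x`, `y`.
#' @param gl A [guidelines()].
#' @param width,height Image dimensions in pixels.
#' @return Data frame `x0, y0, x1, y1` (0-based inclusive pixel bounds),
#'   one row per crowded group; zero rows when nothing is crowded.
#' @export
find_crowded_regions <- function(spots, gl, width, height) {
  empty <- data.frame(x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0))
  if (nrow(spots) < 2L) return(empty)
  crowded <- nn_dist(spots[, c("x", "y")]) < gl$target_nnd_hi
  if (!any(crowded)) return(empty)
  cs <- spots[crowded, c("x", "y"), drop = FALSE]
  grp <- single_linkage_groups(cs, gl$target_nnd_hi)
  pad <- 2 * gl$target_nnd_hi
  boxes <- lapply(unique(grp), function(g) {
    p <- cs[grp == g, , drop = FALSE]
    data.frame(x0 = max(0L, floor(min(p$x) - pad)),
               y0 = max(0L, floor(min(p$y) - pad)),
               x1 = min(width - 1L, ceiling(max(p$x) + pad)),
               y1 = min(height - 1L, ceiling(max(p$y) + pad)))
  })
  do.call(rbind, boxes)
}

region_ok <- function(spots, x0, y0, w, h, gl, display_width) {
  inside <- spots$x >= x0 & spots$x < x0 + w &
    spots$y >= y0 & spots$y < y0 + h
  s <- spots[inside, , drop = FALSE]
  if (nrow(s) > gl$max_spots_per_crop) return(FALSE)
  if (nrow(s) < 2L) return(TRUE)
  scale <- max(1, display_width / w)
  min(nn_dist(s[, c("x", "y")])) * scale >=
    gl$min_display_nnd_frac * display_width
}

#' Recursively subdivide an image into annotatable crops
#'
#' Starting from the full image, any region that is too crowded after
#' upscaling to the display width—more than `max_spots_per_crop` spots, or
#' a minimum displayed nearest-neighbor distance below
#' `min_display_nnd_frac` of the displayed width—is split into the 2x2
#' quadrants of its crowded bounding box, each expanded by a 10% overlap
#' margin, and the quadrants are examined recursively up to `max_depth`.
#' The full image (depth 0) plus all leaf crops form the output; leaves
#' that still violate the guidelines at `max_depth` are flagged
#' `"saturated"` (some spots are so close that no amount of zooming
#' separates them).
#'
#' @param img Numeric matrix.
#' @param spots Data frame of detected spots (`x`, `y`), e.g. from
#'   [log_detect()].
#' @param gl A [guidelines()].
#' @param display_width Width in displayed pixels at the annotation
#'   interface (> 0).
#' @param parent_id Identifier recorded in every crop spec.
#' @param interpolation Upscaling method for crop images.
#' @return List of crops; each element has `spec` (list with `crop_id`,
#'   `parent_id`, `x0`, `y0`, `width`, `height`, `scale`, `depth`,
#'   `flag`) and `image` (the upscaled crop). The first element is always
#'   the full image.
#' @export
recursive_subdivide <- function(img, spots, gl = guidelines(),
                                display_width = 450L, parent_id = "img",
                                interpolation = c("bilinear", "nearest")) {
  assert_image(img)
  stopifnot(display_width > 0)
  interpolation <- match.arg(interpolation)
  w <- img_width(img); h <- img_height(img)

  crops <- list()
  make_crop <- function(crop_id, x0, y0, cw, ch, depth, flag) {
    scale <- max(1, display_width / cw)
    sub <- img[(y0 + 1L):(y0 + ch), (x0 + 1L):(x0 + cw), drop = FALSE]
    disp <- if (scale > 1) resize_image(sub, scale, interpolation) else sub
    list(spec = list(crop_id = crop_id, parent_id = parent_id,
                     x0 = as.integer(x0), y0 = as.integer(y0),
                     width = as.integer(cw), height = as.integer(ch),
                     scale = scale, depth = as.integer(depth), flag = flag),
         image = disp)
  }

  recurse <- function(crop_id, x0, y0, cw, ch, depth) {
    ok <- region_ok(spots, x0, y0, cw, ch, gl, display_width)
    if (ok || depth >= gl$max_depth) {
      if (depth > 0L) {
        crops[[length(crops) + 1L]] <<-
          make_crop(crop_id, x0, y0, cw, ch, depth,
                    if (ok) "ok" else "saturated")
      }
      return(ok)
    }
    inside <- spots$x >= x0 & spots$x < x0 + cw &
      spots$y >= y0 & spots$y < y0 + ch
    s <- spots[inside, , drop = FALSE]
    boxes <- find_crowded_regions(s, gl, x0 + cw, y0 + ch)
    bb <- if (nrow(boxes) > 0L) {
      c(max(x0, min(boxes$x0)), max(y0, min(boxes$y0)),
        min(x0 + cw - 1L, max(boxes$x1)), min(y0 + ch - 1L, max(boxes$y1)))
    } else {
      c(max(x0, floor(min(s$x))), max(y0, floor(min(s$y))),
        min(x0 + cw - 1L, ceiling(max(s$x))),
        min(y0 + ch - 1L, ceiling(max(s$y))))
    }
    bw <- bb[3L] - bb[1L] + 1L; bh <- bb[4L] - bb[2L] + 1L
    hw <- ceiling(bw / 2); hh <- ceiling(bh / 2)
    mx <- ceiling(0.1 * hw); my <- ceiling(0.1 * hh)  # 10% overlap margin
    q <- 0L
    for (qi in 0:1) for (qj in 0:1) {
      q <- q + 1L
      qx0 <- max(x0, bb[1L] + qj * hw - mx)
      qy0 <- max(y0, bb[2L] + qi * hh - my)
      qx1 <- min(x0 + cw - 1L, bb[1L] + (qj + 1L) * hw - 1L + mx)
      qy1 <- min(y0 + ch - 1L, bb[2L] + (qi + 1L) * hh - 1L + my)
      qw <- qx1 - qx0 + 1L; qh <- qy1 - qy0 + 1L
      if (qw < 8L || qh < 8L) next
      if (qw >= cw && qh >= ch) {
        # degenerate split (quadrant did not shrink): emit as leaf
        crops[[length(crops) + 1L]] <<-
          make_crop(paste0(crop_id, ".", q), qx0, qy0, qw, qh, depth + 1L,
                    "saturated")
        next
      }
      recurse(paste0(crop_id, ".", q), qx0, qy0, qw, qh, depth + 1L)
    }
    TRUE
  }

  root_ok <- region_ok(spots, 0L, 0L, w, h, gl, display_width)
  root_flag <- if (root_ok) "ok" else if (gl$max_depth == 0L) "saturated" else "split"
  crops[[1L]] <- make_crop("c0", 0L, 0L, w, h, 0L, root_flag)
  if (!root_ok && gl$max_depth > 0L) recurse("c0", 0L, 0L, w, h, 0L)
  crops
}

#' Crop manifest table
#'
#' @param crops Result of [recursive_subdivide()].
#' @return Data frame
#'   `crop_id, parent_id, x0, y0, width, height, scale, depth, flag`.
#' @export
crop_manifest <- function(crops) {
  do.call(rbind, lapply(crops, function(cr) {
    as.data.frame(cr$spec, stringsAsFactors = FALSE)
  }))
}

#' Map displayed-crop coordinates to the parent frame
#'
#' `parent = displayed / scale + (x0, y0)`; the exact inverse of
#' [map_to_crop()].
#'
#' @param spec A crop spec (list with `x0`, `y0`, `width`, `height`,
#'   `scale`).
#' @param points Data frame with columns `x`, `y` in displayed crop
#'   pixels.
#' @return Data frame with columns `x`, `y` in parent pixels.
#' @export
map_to_parent <- function(spec, points) {
  points <- as_points(points)
  if (nrow(points) > 0L) {
    lim_x <- spec$width * spec$scale
    lim_y <- spec$height * spec$scale
    bad <- points$x < 0 | points$y < 0 | points$x > lim_x | points$y > lim_y
    if (any(bad)) {
      b <- which(bad)[1L]
      stop(sprintf("boundary error: point (%g, %g) outside displayed crop %s",
                   points$x[b], points$y[b], spec$crop_id %||% "?"),
           call. = FALSE)
    }
  }
  data.frame(x = points$x / spec$scale + spec$x0,
             y = points$y / spec$scale + spec$y0)
}

#' Map parent-frame coordinates into displayed-crop coordinates
#'
#' @inheritParams map_to_parent
#' @param points Data frame with columns `x`, `y` in parent pixels.
#' @param clip Drop points outside the crop instead of erroring.
#' @return Data frame with columns `x`, `y` in displayed crop pixels (and,
#'   if `clip`, attribute `"kept"` with the retained row indices).
#' @export
map_to_crop <- function(spec, points, clip = TRUE) {
  points <- as_points(points)
  inside <- points$x >= spec$x0 & points$x < spec$x0 + spec$width &
    points$y >= spec$y0 & points$y < spec$y0 + spec$height
  if (!clip && !all(inside)) {
    stop("point outside crop", call. = FALSE)
  }
  kept <- which(inside)
  out <- data.frame(x = (points$x[kept] - spec$x0) * spec$scale,
                    y = (points$y[kept] - spec$y0) * spec$scale)
  attr(out, "kept") <- kept
  out
}

#' Reassemble per-crop consensus points into the parent frame
#'
#' Maps every crop's points back to parent coordinates and merges
#' duplicates arising from overlapping crops: points within
#' `dedup_radius` of each other (single linkage) are replaced by their
#' group mean.
#'
#' @param points_by_crop Named list (by `crop_id`) of data frames with
#'   columns `x`, `y` in displayed crop coordinates.
#' @param crops Result of [recursive_subdivide()] (or a list of specs).
#' @param dedup_radius Merge radius in parent pixels (> 0).
#' @return Data frame `x, y, n_sources` in parent coordinates.
#' @export
reassemble <- function(points_by_crop, crops, dedup_radius = 2) {
  stopifnot(dedup_radius > 0)
  specs <- lapply(crops, function(cr) if (!is.null(cr$spec)) cr$spec else cr)
  names(specs) <- vapply(specs, function(s) s$crop_id, character(1))
  mapped <- list()
  for (cid in names(points_by_crop)) {
    if (!cid %in% names(specs)) {
      stop("unknown crop_id: ", cid, call. = FALSE)
    }
    pts <- points_by_crop[[cid]]
    if (nrow(pts) > 0L) {
      mapped[[length(mapped) + 1L]] <- map_to_parent(specs[[cid]], pts)
    }
  }
  if (length(mapped) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), n_sources = integer(0)))
  }
  all_pts <- do.call(rbind, mapped)
  grp <- single_linkage_groups(all_pts, dedup_radius)
  out <- do.call(rbind, lapply(split(seq_len(nrow(all_pts)), grp), function(ix) {
    data.frame(x = mean(all_pts$x[ix]), y = mean(all_pts$y[ix]),
               n_sources = length(ix))
  }))
  rownames(out) <- NULL
  out
}
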