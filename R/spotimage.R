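#' Synthetic-image configuration
#'
#' Bundles the knobs of the synthetic spot-image simulator. Defaults
#' emulate a well-prepared single-molecule FISH field of view: a 300x300
#' field with 100 diffraction-limited spots (sigma 1.5 px) at mean SNR 15
#' and a minimum center-to-center spacing of 10 px, which yields a mean
#' nearest-neighbor distance around 15 px.
#'
#' @param n_spots Number of spots (>= 0).
#' @param snr_mean Mean target signal-to-noise ratio (> 0). A spot's SNR is
#'   its Gaussian amplitude above local background divided by the robust
#'   background standard deviation (see [measure_snr()]).
#' @param snr_spread Standard deviation of per-spot target SNR (>= 0).
#' @param sigma Gaussian spot width in pixels; a scalar or one value per spot.
#' @param min_nnd Minimum pairwise center distance in pixels (>= 0).
#' @param noise_mean,noise_std,texture_scale Background model: Gaussian
#'   noise around `noise_mean`; `texture_scale > 0` low-pass filters the
#'   noise at that scale (then restores `noise_std`) to mimic structured
#'   background.
#' @param invert If `TRUE`, the rendered image is inverted (dark spots on a
#'   light background) after spot placement.
#' @param seed Integer seed; every stochastic step is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_spots = 100L, snr_mean = 15, snr_spread = 2,
                         sigma = 1.5, min_nnd = 10, noise_mean = 100,
                         noise_std = 10, texture_scale = 0, invert = FALSE,
                         seed = 1L) {
  stopifnot(n_spots >= 0, snr_mean > 0, snr_spread >= 0, all(sigma > 0),
            min_nnd >= 0, noise_std >= 0, texture_scale >= 0)
  structure(list(n_spots = as.integer(n_spots), snr_mean = snr_mean,
                 snr_spread = snr_spread, sigma = sigma, min_nnd = min_nnd,
                 noise_mean = noise_mean, noise_std = noise_std,
                 texture_scale = texture_scale, invert = isTRUE(invert),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic noise background
#'
#' Gaussian noise around `noise_mean`; with `texture_scale > 0` the noise
#' field is low-pass filtered at that scale and rescaled so the global
#' standard deviation still equals `noise_std`, giving a smoothly textured
#' background. Intensities are clamped at zero.
#'
#' @param width,height Image dimensions in pixels (>= 16).
#' @param noise_mean Background mean intensity.
#' @param noise_std Background standard deviation (>= 0).
#' @param texture_scale Low-pass scale in pixels (0 = white noise).
#' @param seed Integer seed; the same call with the same seed is
#'   bit-identical.
#' @return Numeric matrix `height` x `width`.
#' @export
generate_background <- function(width, height, noise_mean = 100,
                                noise_std = 10, texture_scale = 0,
                                seed = 1L) {
  if (width < 16 || height < 16) {
    stop("background dimensions must be at least 16x16", call. = FALSE)
  }
  stopifnot(noise_std >= 0, texture_scale >= 0)
  if (noise_std == 0) return(matrix(noise_mean, height, width))
  with_seed(seed, {
    z <- matrix(stats::rnorm(width * height), height, width)
    if (texture_scale > 0) {
      z <- gaussian_blur(z, texture_scale)
      z <- (z - mean(z)) / stats::sd(z)
    }
    pmax(noise_mean + noise_std * z, 0)
  })
}

#' Sample spot locations with a minimum-spacing constraint
#'
#' Uniform rejection sampling: each accepted center is at least
#' `3 * sigma` from every border (so spots are fully rendered and
#' fittable) and at least `min_nnd` from every previously accepted center.
#'
#' @param config A [synth_config()].
#' @param width,height Image dimensions in pixels.
#' @return Data frame with columns `x`, `y` (0-based pixel coordinates),
#'   one row per spot.
#' @details Sampling aborts with a packing error after
#'   `10000 * n_spots` total proposals; that bound is hit only when
#'   `min_nnd` is geometrically infeasible for `n_spots` in the usable
#'   area.
#' @export
sample_spot_locations <- function(config, width, height) {
  n <- config$n_spots
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  sig <- rep_len(config$sigma, n)
  margin <- 3 * sig
  if (any(width - 1 - 2 * margin <= 0) || any(height - 1 - 2 * margin <= 0)) {
    stop("image too small for border margin 3*sigma", call. = FALSE)
  }
  with_seed(config$seed, {
    xs <- numeric(n); ys <- numeric(n)
    accepted <- 0L
    proposals <- 0L
    cap <- 10000 * n
    while (accepted < n) {
      if (proposals >= cap) {
        stop(sprintf(
          "packing error: could not place %d spots with min_nnd = %g in a %dx%d image after %d proposals",
          n, config$min_nnd, width, height, cap), call. = FALSE)
      }
      i <- accepted + 1L
      px <- stats::runif(1, margin[i], width - 1 - margin[i])
      py <- stats::runif(1, margin[i], height - 1 - margin[i])
      proposals <- proposals + 1L
      ok <- accepted == 0L ||
        all((xs[seq_len(accepted)] - px)^2 + (ys[seq_len(accepted)] - py)^2 >=
              config$min_nnd^2)
      if (ok) {
        accepted <- i
        xs[i] <- px; ys[i] <- py
      }
    }
    data.frame(x = xs, y = ys)
  })
}

# Robust (MAD-based) standard deviation of the annulus [4*sigma, 8*sigma]
# around (x, y); errors if the annulus lies fully outside the image.
annulus_robust_sd <- function(img, x, y, sigma) {
  r_in <- 4 * sigma; r_out <- 8 * sigma
  h <- img_height(img); w <- img_width(img)
  cols <- max(0, floor(x - r_out)):min(w - 1, ceiling(x + r_out))
  rows <- max(0, floor(y - r_out)):min(h - 1, ceiling(y + r_out))
  if (length(cols) == 0L || length(rows) == 0L) {
    stop("boundary error: annulus falls fully outside the image", call. = FALSE)
  }
  cc <- outer(rep(1, length(rows)), cols)
  rr <- outer(rows, rep(1, length(cols)))
  d2 <- (cc - x)^2 + (rr - y)^2
  sel <- d2 >= r_in^2 & d2 <= r_out^2
  if (!any(sel)) {
    stop("boundary error: annulus falls fully outside the image", call. = FALSE)
  }
  vals <- img[cbind(rr[sel] + 1L, cc[sel] + 1L)]
  stats::mad(vals, constant = 1.4826)
}

#' Measure a spot's signal-to-noise ratio
#'
#' SNR is defined as `A / sd_bg`: `A` is the fitted Gaussian amplitude
#' above the local background offset (least-squares fit in a window of
#' half-width `ceil(4*sigma)`, see [fit_gaussian_sigma()]), and `sd_bg` is
#' the robust standard deviation (1.4826 x median absolute deviation) of
#' the annulus `[4*sigma, 8*sigma]` around the center. The ratio is
#' invariant under rescaling of the image intensities.
#'
#' @param img Numeric matrix.
#' @param x,y Spot center, 0-based pixel coordinates.
#' @param sigma Expected spot width in pixels (> 0).
#' @return A single SNR value (0 when the image is locally flat).
#' @export
measure_snr <- function(img, x, y, sigma) {
  assert_image(img)
  stopifnot(sigma > 0, x >= 0, y >= 0,
            x < img_width(img), y < img_height(img))
  sd_bg <- annulus_robust_sd(img, x, y, sigma)
  fit <- fit_gaussian_sigma(img, x, y,
                            window_halfwidth = max(3L, ceiling(4 * sigma)))
  if (sd_bg < 1e-12) {
    return(if (abs(fit$amplitude) < 1e-9) 0 else Inf)
  }
  fit$amplitude / sd_bg
}

#' Render Gaussian spots onto a background
#'
#' Adds an isotropic 2-D Gaussian `A * exp(-((x-x0)^2 + (y-y0)^2) /
#' (2 sigma^2))` for every location. Each spot's amplitude is calibrated
#' to its target SNR drawn from `N(snr_mean, snr_spread)` (truncated at
#' 0.5): `A = snr * sd_bg` where `sd_bg` is the robust noise level of the
#' background annulus around the spot, measured before any spot is added
#' (so calibration is not contaminated by the spots themselves). On a
#' (near-)noiseless background the amplitude falls back to the target SNR
#' in intensity units.
#'
#' @param background Numeric matrix; not modified.
#' @param locations Data frame with columns `x`, `y` (see
#'   [sample_spot_locations()]).
#' @param config A [synth_config()].
#' @return List with `image` (background + spots, inverted if
#'   `config$invert`) and `truth`, a data frame
#'   `spot_id, x, y, sigma, amplitude, snr`.
#' @export
render_spots <- function(background, locations, config) {
  assert_image(background, "background")
  n <- nrow(locations)
  sig <- rep_len(config$sigma, max(n, 1L))
  img <- background
  truth <- data.frame(spot_id = character(0), x = numeric(0), y = numeric(0),
                      sigma = numeric(0), amplitude = numeric(0),
                      snr = numeric(0), stringsAsFactors = FALSE)
  if (n > 0L) {
    w <- img_width(background); h <- img_height(background)
    if (any(locations$x < 0) || any(locations$x >= w) ||
        any(locations$y < 0) || any(locations$y >= h)) {
      stop("spot locations outside the image", call. = FALSE)
    }
    snr_target <- with_seed(derive_seed(config$seed, "snr"), {
      pmax(stats::rnorm(n, config$snr_mean, config$snr_spread), 0.5)
    })
    amp <- numeric(n)
    for (i in seq_len(n)) {
      sd_bg <- annulus_robust_sd(background, locations$x[i], locations$y[i],
                                 sig[i])
      amp[i] <- if (sd_bg < 1e-12) snr_target[i] else snr_target[i] * sd_bg
      img <- add_gaussian(img, locations$x[i], locations$y[i], sig[i], amp[i])
    }
    truth <- data.frame(spot_id = sprintf("s%04d", seq_len(n)),
                        x = locations$x, y = locations$y, sigma = sig[seq_len(n)],
                        amplitude = amp, snr = snr_target,
                        stringsAsFactors = FALSE)
  }
  if (config$invert) img <- invert_image(img)
  list(image = img, truth = truth)
}

# Stamp one Gaussian into the image (window truncated at 6 sigma; the
# truncated mass is below 2e-8 of the peak).
add_gaussian <- function(img, x, y, sigma, amplitude) {
  w <- img_width(img); h <- img_height(img)
  r <- ceiling(6 * sigma)
  cols <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
  rows <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
  gx <- exp(-(cols - x)^2 / (2 * sigma^2))
  gy <- exp(-(rows - y)^2 / (2 * sigma^2))
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    amplitude * (gy %o% gx)
  img
}

#' Simulate a complete synthetic spot image
#'
#' Convenience wrapper: background, spot placement and rendering from one
#' configuration.
#'
#' @param config A [synth_config()].
#' @param width,height Image dimensions in pixels.
#' @return List of class `spot_sim` with `image`, `truth` (see
#'   [render_spots()]), `config`, `width`, `height`.
#' @examples
#' sim <- simulate_spot_image(synth_config(n_spots = 20, seed = 7),
#'                            width = 128, height = 128)
#' nrow(sim$truth)
#' @export
simulate_spot_image <- function(config = synth_config(), width = 300L,
                                height = 300L) {
  bg <- generate_background(width, height, config$noise_mean,
                            config$noise_std, config$texture_scale,
                            seed = derive_seed(config$seed, "background"))
  loc <- sample_spot_locations(config, width, height)
  rend <- render_spots(bg, loc, config)
  structure(list(image = rend$image, truth = rend$truth, config = config,
                 width = as.integer(width), height = as.integer(height)),
            class = "spot_sim")
}

#' @export
print.spot_sim <- function(x, ...) {
  cat(sprintf("Synthetic spot image: %dx%d px, %d spots, target SNR %.3g (sd %.3g), sigma %s, min NND %g px, seed %d\n",
              x$width, x$height, nrow(x$truth), x$config$snr_mean,
              x$config$snr_spread,
              paste(signif(unique(rep_len(x$config$sigma, max(1, nrow(x$truth)))), 3), collapse = "/"),
              x$config$min_nnd, x$config$seed))
  invisible(x)
}

#' Write / read a ground-truth spot table
#'
#' CSV with header `spot_id,x,y,sigma,amplitude,snr`; coordinates 0-based.
#'
#' @param truth Data frame as returned in `spot_sim$truth`.
#' @param path Output path.
#' @return `path` (write) or the data frame (read), invisibly for write.
#' @export
write_spot_csv <- function(truth, path) {
  utils::write.csv(truth[, c("spot_id", "x", "y", "sigma", "amplitude", "snr")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
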