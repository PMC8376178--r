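#' Gaussian blur of an image
#'
#' Thin wrapper around [EBImage::gblur()] with replicated borders, keeping
#' the package's matrix convention.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  assert_image(img)
  stopifnot(sigma > 0)
  as.matrix(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
}

# Negative Laplacian (4-connected): positive response at bright peaks.
laplacian_filter <- function(img) {
  k <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3L, 3L)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

#' Invert an image
#'
#' Returns `max(img) - img`, turning bright spots on a dark background into
#' dark spots on a light background (and vice versa). Useful for testing
#' whether annotators perform differently on inverted displays.
#'
#' @param img Numeric matrix.
#' @return Inverted matrix; pairwise pixel differences are preserved up to
#'   sign, so `invert_image(invert_image(x))` equals `x` shifted by a
#'   constant (exactly `x` when `min(x) == 0`).
#' @export
invert_image <- function(img) {
  assert_image(img)
  max(img) - img
}

#' Rescale an image for 8-bit display
#'
#' Linear rescale to `[0, 255]` after clipping to the `[0.1, 99.9]`
#' percentile range, the normalization used when exporting crops for
#' annotation.
#'
#' @param img Numeric matrix.
#' @param probs Lower/upper clip percentiles as fractions.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
display_normalize <- function(img, probs = c(0.001, 0.999)) {
  assert_image(img)
  q <- stats::quantile(img, probs = probs, names = FALSE)
  if (q[2L] <= q[1L]) return(matrix(0, nrow(img), ncol(img)))
  x <- pmin(pmax(img, q[1L]), q[2L])
  (x - q[1L]) / (q[2L] - q[1L]) * 255
}

#' Read a grayscale image or z-stack
#'
#' Reads TIFF or PNG via [EBImage::readImage()]. Multi-frame TIFFs are
#' returned as a list of matrices (one per z-plane); single-frame images as
#' one matrix. Intensities are rescaled by `scale` (EBImage reads into
#' `[0, 1]`).
#'
#' @param path File path (.tif/.tiff/.png).
#' @param scale Multiplier applied to the stored `[0, 1]` intensities;
#'   the package's own writers use 65535 (16-bit-like units).
#' @return Matrix or list of matrices (rows = y, columns = x).
#' @export
read_image <- function(path, scale = 65535) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- EBImage::readImage(path)
  dat <- EBImage::imageData(im)
  if (length(dim(dat)) == 2L) return(t(dat) * scale)
  if (length(dim(dat)) == 3L) {
    return(lapply(seq_len(dim(dat)[3L]), function(k) t(dat[, , k]) * scale))
  }
  stop("unsupported image layout in ", path, call. = FALSE)
}

#' Write an image to TIFF (analysis) or PNG (display)
#'
#' TIFF output stores `img / scale` as floating point, so the default
#' `scale = 65535` gives a lossless round trip with [read_image()] for
#' 16-bit-range data. PNG output applies [display_normalize()] and writes
#' 8-bit.
#'
#' @param img Numeric matrix.
#' @param path Output path; format chosen by extension.
#' @param scale Intensity divisor for TIFF output.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, scale = 65535) {
  assert_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(EBImage::Image(t(img / scale)), path,
                        type = "tiff", bits.per.sample = 32L)
  } else if (ext == "png") {
    EBImage::writeImage(EBImage::Image(t(display_normalize(img) / 255)), path,
                        type = "png", bits.per.sample = 8L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

# Bilinear (default) or nearest-neighbor upscaling by an integer-free factor.
resize_image <- function(img, factor, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nr <- max(1L, round(nrow(img) * factor))
  nc <- max(1L, round(ncol(img) * factor))
  as.matrix(EBImage::resize(img, w = nr, h = nc,
                            filter = if (method == "bilinear") "bilinear" else "none"))
}
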