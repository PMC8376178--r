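#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout: images are base R matrices with
# rows = y (increasing downward) and columns = x (increasing rightward);
# coordinates are 0-based with pixel centers at integers, so pixel (x, y)
# lives at mat[y + 1, x + 1]. All CSV output uses this convention.

#' Evaluate an expression with a fixed RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic 31-bit string hash (polynomial rolling hash), used to derive
# independent per-worker random streams: adding workers never perturbs the
# streams of existing ones.
str_hash31 <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, id) {
  as.integer(bitwXor(as.integer(seed %% 2147483647L), str_hash31(as.character(id))) %% 2147483647L)
}

assert_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have positive dimensions", arg), call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop(sprintf("`%s` contains non-finite intensities", arg), call. = FALSE)
  }
  invisible(img)
}

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

# Pairwise Euclidean distances between rows of two 2-column matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1L], b[, 1L], "-")
  dy <- outer(a[, 2L], b[, 2L], "-")
  sqrt(dx * dx + dy * dy)
}

# Nearest-neighbor distance for each row of a 2-column point matrix.
nn_dist <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) return(rep(Inf, n))
  d <- cross_dist(pts, pts)
  diag(d) <- Inf
  apply(d, 1L, min)
}

# Single-linkage grouping of 2-D points at a cut radius; returns integer
# group labels. Pairs in different groups are > radius apart in
# single-linkage distance.
single_linkage_groups <- function(pts, radius) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(pts), method = "single")
  stats::cutree(hc, h = radius)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
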