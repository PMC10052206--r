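# Scatter-plot pixelation: the entropy estimator's discretization layer.
# Two-variable windows are turned into b x b density images on an
# equal-frequency (rank) grid, which makes the estimator invariant to any
# strictly monotone rescaling of either variable and insensitive to outliers.

#' Mesh side of the scatter-plot pixelation
#'
#' The number of pixels per side for a window of `M` samples:
#' `b = floor(sqrt(M))`, so that a 100-sample window is pixelated on a
#' 10 x 10 mesh and each pixel holds on the order of one sample per cell
#' under independence.
#'
#' @param M Number of data samples in the window (>= 4).
#' @return Integer number of pixels per side (>= 2).
#' @export
#' @examples
#' mesh_side(100)  # 10
mesh_side <- function(M) {
  .check(is.numeric(M) && length(M) == 1 && is.finite(M),
         "M must be a single number")
  .check(M >= 4, "insufficient samples: need M >= 4 for pixelation")
  as.integer(floor(sqrt(M) + 1e-9))
}

# equal-frequency bin index per observation; ties broken by stable input order
rank_bins <- function(x, b) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * b / n) + 1)
}

#' Shannon entropy of a discrete distribution
#'
#' `H = -sum(p * log2(p))` in bits; zero cells contribute nothing. This is the
#' elementary quantity from which all entries of the entropy matrix are built.
#'
#' @param p Vector of probabilities (non-negative, summing to at most 1; a
#'   sub-distribution is allowed and its missing mass is ignored).
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2 bits
shannon_entropy <- function(p) {
  .check(is.numeric(p), "p must be numeric")
  .check(all(p >= 0), "negative probability")
  .check(sum(p) <= 1 + 1e-9, "probabilities must sum to at most 1")
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# entropy (bits) straight from integer counts
entropy_counts <- function(cnt, n) {
  p <- cnt[cnt > 0] / n
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

#' Pixelate a two-variable scatter plot on a rank grid
#'
#' Partitions each axis into `b = floor(sqrt(M))` equal-frequency rank bins
#' (ties broken by input order) and counts the samples falling into each of
#' the `b x b` pixels. The resulting density image `m / M` is the object on
#' which structure (generalized correlation) is detected: a structured pair
#' concentrates mass on few pixels, an independent pair spreads it evenly.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either coordinate are dropped before pixelation.
#' @return An object of class `qct_pixel_image`: list with `b`, `M`,
#'   `counts` (b x b integer matrix, rows = x bins), `density` (`counts / M`),
#'   and the per-axis bin assignments `bx`, `by`.
#' @export
#' @examples
#' img <- rank_pixelate(1:100, (1:100)^3)  # monotone: diagonal image
#' diag(img$counts)
rank_pixelate <- function(x, y) {
  .check(length(x) == length(y), "x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  M <- length(x)
  b <- mesh_side(M)
  bx <- rank_bins(x, b)
  by <- rank_bins(y, b)
  counts <- matrix(tabulate((bx - 1L) * b + by, nbins = b * b),
                   nrow = b, ncol = b, byrow = TRUE)
  structure(list(b = b, M = M, counts = counts, density = counts / M,
                 bx = bx, by = by),
            class = "qct_pixel_image")
}

#' @export
print.qct_pixel_image <- function(x, ...) {
  cat(sprintf("Pixel image: %d x %d mesh over %d samples (occupied pixels: %d)\n",
              x$b, x$b, x$M, sum(x$counts > 0)))
  invisible(x)
}
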