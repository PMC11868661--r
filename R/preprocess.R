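#' Convert linear intensity to dB and back
#'
#' Intensity profiles use the `10 log10` convention (they are squared
#' amplitudes). Non-positive values, and values below the floor, are clamped
#' to `floor_db`.
#'
#' @param x Linear intensity (vector or matrix).
#' @param floor_db Clamp level in dB; values mapping below it are set to it.
#' @return dB values, same shape.
#' @export
to_db <- function(x, floor_db = -Inf) {
  out <- suppressWarnings(10 * log10(x))
  out[!is.finite(out) | out < floor_db] <- floor_db
  out
}

#' @rdname to_db
#' @param db dB values.
#' @export
from_db <- function(db) 10^(db / 10)

#' Subtract the air-region bias from a B-scan
#'
#' Estimates the additive background as the median intensity over the air
#' rows (depth pixels above the sample surface) and subtracts it everywhere,
#' unless that median is below the image minimum, in which case the scan is
#' returned unchanged.
#'
#' @param bscan Linear-intensity matrix (depth x lateral) or vector.
#' @param air_rows Depth-pixel indices treated as air; must be non-empty and
#'   within the scan.
#' @param bias Optional precomputed background estimate (e.g. the joint air
#'   median of a scan pair); when supplied, `air_rows` is ignored for the
#'   estimate but the skip condition is still checked against this scan.
#' @return Debiased scan (may contain non-positive values; these are handled
#'   by the dB floor downstream).
#' @export
debias <- function(bscan, air_rows, bias = NULL) {
  air_rows <- as.integer(air_rows)
  p <- if (is.matrix(bscan)) nrow(bscan) else length(bscan)
  if (length(air_rows) == 0) stop("air_rows must be non-empty")
  if (any(air_rows < 1) || any(air_rows > p))
    stop("air_rows outside the depth range")
  med <- if (!is.null(bias)) bias else
    stats::median(if (is.matrix(bscan)) bscan[air_rows, ] else bscan[air_rows])
  if (med < min(bscan)) return(bscan)
  bscan - med
}

# 1-D Gaussian kernel of a given size; even sizes use the MATLAB-style
# center at (size+1)/2 so a size-10 kernel is supported
gaussian_kernel_1d <- function(sigma, size) {
  if (sigma == 0) return(1)
  c0 <- (size + 1) / 2
  k <- exp(-((seq_len(size) - c0)^2) / (2 * sigma^2))
  k / sum(k)
}

# pad a matrix by symmetric reflection (edge pixel not repeated beyond once)
pad_symmetric <- function(x, top, bottom, left, right) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rev(seq_len(top)), seq_len(nr), nr + 1 - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(nc), nc + 1 - seq_len(right))
  x[ri, ci, drop = FALSE]
}

#' Rotationally symmetric 2-D Gaussian filter
#'
#' Linear, shift-invariant smoothing by a separable Gaussian kernel with
#' symmetric-reflection boundary handling. `sigma = 0` is the identity.
#'
#' @param bscan Numeric matrix (depth x lateral) or vector.
#' @param sigma Standard deviation of the kernel, pixels (>= 0).
#' @param size Kernel size in pixels; defaults to `2*ceiling(3*sigma) + 1`.
#'   Even sizes are allowed (kernel centered at `(size+1)/2`).
#' @return Filtered scan, same shape.
#' @export
gaussian_filter_2d <- function(bscan, sigma, size = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(bscan)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  size <- as.integer(size)
  stopifnot(size >= 1)
  vec <- !is.matrix(bscan)
  x <- if (vec) matrix(bscan, ncol = 1) else bscan
  k <- gaussian_kernel_1d(sigma, size)
  # correlation offsets: tap j multiplies the pixel at relative offset
  # j - ceil((size+1)/2 - 0.5); with center c0 = (size+1)/2 the left pad is
  # floor(size/2) for odd, size/2 for even (MATLAB imfilter convention)
  left <- ceiling((size - 1) / 2)
  right <- size - 1L - left
  kp <- ncol(x) > 1L
  xp <- pad_symmetric(x, left, right, if (kp) left else 0L,
                      if (kp) right else 0L)
  out <- matrix(0, nrow(x), ncol(xp))
  for (j in seq_len(size))  # vertical pass
    out <- out + k[j] * xp[(j - 1) + seq_len(nrow(x)), , drop = FALSE]
  if (kp) {
    out2 <- matrix(0, nrow(x), ncol(x))
    for (j in seq_len(size))  # horizontal pass
      out2 <- out2 + k[j] * out[, (j - 1) + seq_len(ncol(x)), drop = FALSE]
    out <- out2
  }
  if (vec) as.numeric(out) else out
}

#' Laterally average a B-scan
#'
#' Per-depth arithmetic mean over lateral columns, computed in linear
#' intensity. Conversion to dB is a separate, subsequent step.
#'
#' @param bscan Linear-intensity matrix (depth x lateral) or vector.
#' @return Numeric vector of length `nrow(bscan)`.
#' @export
lateral_average <- function(bscan) {
  if (!is.matrix(bscan)) return(as.numeric(bscan))
  stopifnot(ncol(bscan) >= 1)
  rowMeans(bscan)
}

#' Preprocessing specification
#'
#' @param air_rows Depth pixels treated as air for debiasing.
#' @param speckle_sigma Standard deviation of the 2-D speckle-suppression
#'   Gaussian, pixels (default 0.5).
#' @param smooth_size Size of the low-pass Gaussian kernel, pixels
#'   (default 10).
#' @param smooth_sigma Standard deviation of the low-pass Gaussian, pixels
#'   (default 5).
#' @param db_floor dB floor relative to the image maximum used when
#'   converting to dB (default -30).
#' @return An object of class `oct_preprocess_spec`.
#' @export
preprocess_spec <- function(air_rows, speckle_sigma = 0.5,
                            smooth_size = 10L, smooth_sigma = 5,
                            db_floor = -30) {
  stopifnot(speckle_sigma >= 0, smooth_sigma >= 0, smooth_size >= 1)
  structure(
    list(air_rows = as.integer(air_rows), speckle_sigma = speckle_sigma,
         smooth_size = as.integer(smooth_size), smooth_sigma = smooth_sigma,
         db_floor = db_floor),
    class = "oct_preprocess_spec"
  )
}

#' Clean and smooth a measured B-scan
#'
#' Pipeline used before envelope extraction: debias by the air-region median
#' (linear), suppress speckle with a small Gaussian (linear), convert to dB
#' with a max-relative floor, and low-pass smooth in dB.
#'
#' @param bscan Linear-intensity matrix (depth x lateral).
#' @param spec A [preprocess_spec()].
#' @return List with `linear` (debiased, speckle-filtered linear scan) and
#'   `db` (smoothed dB scan).
#' @export
preprocess_bscan <- function(bscan, spec) {
  stopifnot(inherits(spec, "oct_preprocess_spec"))
  x <- debias(bscan, spec$air_rows)
  if (spec$speckle_sigma > 0) x <- gaussian_filter_2d(x, spec$speckle_sigma)
  floor_abs <- to_db(max(x)) + spec$db_floor
  xdb <- to_db(x, floor_db = floor_abs)
  if (spec$smooth_sigma > 0)
    xdb <- gaussian_filter_2d(xdb, spec$smooth_sigma, spec$smooth_size)
  list(linear = x, db = xdb)
}
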