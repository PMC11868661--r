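#' Correct a scan by an estimated combined function
#'
#' Elementwise division of a linear-intensity scan by the per-depth envelope
#' estimate, removing the depth-dependent system response up to the
#' unidentifiable overall scale.
#'
#' @param scan Linear-intensity matrix (depth x lateral) or vector.
#' @param g A `g_estimate` or a strictly positive numeric vector of
#'   per-depth values (length = depth pixels).
#' @return Corrected scan, same shape.
#' @export
correct_scan <- function(scan, g) {
  g_lin <- if (inherits(g, "g_estimate")) g$g_lin else g
  p <- if (is.matrix(scan)) nrow(scan) else length(scan)
  stopifnot(length(g_lin) == p, all(g_lin > 0))
  scan / g_lin
}

#' RMSE between two vertically shifted A-scans (dB)
#'
#' Root mean squared dB difference `S1(i) - S2(i + m)` over the
#' `p - m` overlapping pixels; the non-overlapping pixels are excluded.
#' Invariant to adding a constant to both scans (and hence to the
#' normalization of any `g` used to correct them).
#'
#' @param scan1_db,scan2_db dB A-scans (numeric vectors of equal length).
#' @param m Alignment shift in pixels (`0 <= m < p`).
#' @param mask Optional logical vector over the overlap (length `p - m`)
#'   selecting pixels to include (e.g. to drop floor-clamped depths);
#'   default includes the full overlap.
#' @return RMSE in dB.
#' @export
rmse_aligned <- function(scan1_db, scan2_db, m, mask = NULL) {
  p <- length(scan1_db)
  stopifnot(length(scan2_db) == p, m >= 0)
  if (m >= p) stop("shift m must be smaller than the scan length")
  m <- as.integer(m)
  n <- p - m
  d <- scan1_db[seq_len(n)] - scan2_db[m + seq_len(n)]
  if (!is.null(mask)) {
    stopifnot(length(mask) == n)
    d <- d[mask]
  }
  sqrt(mean(d^2))
}

#' Per-lateral-position RMSE between two B-scans (dB)
#'
#' Applies [rmse_aligned()] column-wise: the metric for every corresponding
#' pair of A-scans at each lateral position.
#'
#' @param bscan1_db,bscan2_db dB B-scans (matrices of equal dimensions).
#' @param m Alignment shift in pixels.
#' @return Numeric vector of per-column RMSE values, length = lateral width.
#' @export
rmse_per_lateral <- function(bscan1_db, bscan2_db, m) {
  stopifnot(is.matrix(bscan1_db), identical(dim(bscan1_db), dim(bscan2_db)))
  vapply(seq_len(ncol(bscan1_db)), function(j)
    rmse_aligned(bscan1_db[, j], bscan2_db[, j], m), numeric(1))
}

#' Correct a scan pair and report pre/post similarity
#'
#' Corrects both laterally averaged A-scans of a shifted pair by an
#' estimated `g`, and reports the aligned RMSE before and after correction,
#' plus the per-lateral-position RMSE when full B-scans are supplied.
#'
#' @param scans An `oct_pair` or list of two linear B-scans / A-scans.
#' @param g A `g_estimate` or per-depth envelope vector.
#' @param m Pixel shift (taken from the `oct_pair` when one is supplied).
#' @return An object of class `correction_report`: corrected averaged
#'   A-scans (linear and dB), `rmse_uncorrected` and `rmse_corrected` (dB),
#'   `per_lateral_rmse` (corrected, per column; `NULL` for vector input)
#'   and `overlap` (number of pixels compared).
#' @export
correction_report <- function(scans, g, m = NULL) {
  if (inherits(scans, "oct_pair")) {
    m <- scans$shifts[2] - scans$shifts[1]
    scans <- scans$scans[1:2]
  }
  stopifnot(length(scans) == 2, !is.null(m))
  g_lin <- if (inherits(g, "g_estimate")) g$g_lin else g
  avg <- lapply(scans, lateral_average)
  corr <- lapply(avg, correct_scan, g = g_lin)
  avg_db <- lapply(avg, to_db)
  corr_db <- lapply(corr, to_db)
  per_lat <- NULL
  if (is.matrix(scans[[1]])) {
    c1 <- to_db(correct_scan(scans[[1]], g_lin))
    c2 <- to_db(correct_scan(scans[[2]], g_lin))
    per_lat <- rmse_per_lateral(c1, c2, m)
  }
  structure(
    list(corrected = corr, corrected_db = corr_db,
         rmse_uncorrected = rmse_aligned(avg_db[[1]], avg_db[[2]], m),
         rmse_corrected = rmse_aligned(corr_db[[1]], corr_db[[2]], m),
         per_lateral_rmse = per_lat,
         overlap = length(avg[[1]]) - m, m = m),
    class = "correction_report"
  )
}
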