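#' Attenuation coefficient by curve fitting (CF method)
#'
#' Least-squares slope of the natural-log corrected intensity versus
#' physical depth inside a homogeneous window; under single scattering the
#' slope equals `-2 mu`, so `mu = -slope / 2`. The optical depth axis is
#' divided by the refractive index to obtain physical depth.
#'
#' @param ascan Corrected linear-intensity A-scan (vector, length `grid$p`).
#' @param window Integer pixel range to fit over (>= 3 pixels, strictly
#'   positive intensities).
#' @param grid The [acquisition_grid()].
#' @param refractive_index Sample refractive index (default 1).
#' @return An object of class `ac_fit`: `mu` (mm^-1), `window`,
#'   `refractive_index`, `slope`, `r_squared`.
#' @export
ac_curve_fit <- function(ascan, window, grid, refractive_index = 1) {
  stopifnot(inherits(grid, "oct_grid"), refractive_index > 0)
  window <- as.integer(window)
  if (length(window) < 3) stop("fit window must span at least 3 pixels")
  if (any(window < 1) || any(window > grid$p))
    stop("fit window outside the grid")
  y <- ascan[window]
  if (any(y <= 0))
    stop("non-positive intensities in the fit window; cannot take log")
  zphys <- grid$z[window] / refractive_index
  ly <- log(y)
  fit <- stats::lm(ly ~ zphys)
  slope <- unname(stats::coef(fit)[2])
  # r^2 computed directly; summary.lm warns on numerically perfect fits
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  structure(
    list(mu = -slope / 2, window = window,
         refractive_index = refractive_index, slope = slope,
         r_squared = r2),
    class = "ac_fit"
  )
}

#' Per-layer CF attenuation estimates
#'
#' Applies [ac_curve_fit()] to one window per layer and returns a tidy
#' table.
#'
#' @param ascan Corrected linear-intensity A-scan.
#' @param windows List of integer pixel ranges, one per layer.
#' @param grid The [acquisition_grid()].
#' @param refractive_index Sample refractive index.
#' @return Tibble with columns `layer`, `mu`, `window_start`, `window_end`,
#'   `r_squared`.
#' @export
ac_layers <- function(ascan, windows, grid, refractive_index = 1) {
  fits <- lapply(windows, ac_curve_fit, ascan = ascan, grid = grid,
                 refractive_index = refractive_index)
  tibble::tibble(
    layer = seq_along(fits),
    mu = vapply(fits, `[[`, numeric(1), "mu"),
    window_start = vapply(windows, min, numeric(1)),
    window_end = vapply(windows, max, numeric(1)),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared")
  )
}

#' Depth-resolved attenuation coefficient (DRC method)
#'
#' Per-pixel single-scattering estimator: each pixel's attenuation is its
#' intensity divided by twice the pixel pitch times the summed intensity of
#' all deeper pixels, `mu(i) = I(i) / (2 Delta sum_{j > i} I(j))`. Assumes
#' the signal is substantially attenuated within the imaging range; pixels
#' with an empty (non-positive) tail are returned as `NA`. The estimator is
#' invariant to the overall intensity scale.
#'
#' @param scan Corrected linear-intensity B-scan matrix or A-scan vector.
#' @param grid The [acquisition_grid()].
#' @param refractive_index Sample refractive index (scales the physical
#'   pixel pitch).
#' @return Per-pixel `mu` in mm^-1, same shape as `scan`; the last pixel
#'   and any pixel with no remaining tail are `NA`.
#' @export
ac_depth_resolved <- function(scan, grid, refractive_index = 1) {
  stopifnot(inherits(grid, "oct_grid"), refractive_index > 0)
  delta <- grid$pitch / refractive_index
  one <- function(v) {
    # tail sums: sum over j > i
    tails <- rev(cumsum(rev(v))) - v
    mu <- v / (2 * delta * tails)
    mu[tails <= 0] <- NA_real_
    mu
  }
  if (is.matrix(scan)) apply(scan, 2, one) else one(scan)
}

#' Default per-layer fit windows for a simulated phantom
#'
#' Deterministic windows for per-layer CF fitting on a known phantom: each
#' layer's pixel interior shrunk by a safety margin on both sides, and
#' additionally truncated where the noise-free floored profile of the scan
#' reaches the dB clamp (a clamped tail carries no attenuation
#' information).
#'
#' @param phantom The [layered_phantom()].
#' @param grid The [acquisition_grid()].
#' @param det [detection_params()] (used to locate the floor crossing).
#' @param margin Pixels removed at each end of every layer (default 5).
#' @param floor_db Simulator signal floor in dB (default -30).
#' @return List of integer pixel ranges, one per layer.
#' @export
phantom_fit_windows <- function(phantom, grid, det = detection_params(),
                                margin = 5L, floor_db = -30) {
  prof <- ideal_ascan(phantom, grid, det)
  floor_level <- max(prof) * 10^(floor_db / 10)
  above <- prof > floor_level
  b <- phantom$boundaries
  lapply(seq_along(phantom$mu), function(l) {
    idx <- which(grid$z >= b[l] & grid$z < b[l + 1] & above)
    if (length(idx) <= 2 * margin + 2)
      stop("layer ", l, " too thin for the requested margin")
    (min(idx) + margin):(max(idx) - margin)
  })
}
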