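#' Fit the two-parameter confocal model to shifted-scan ratio data
#'
#' The classical baseline: the dB data vector
#' `y(i) = I1(i)_dB - I2(i+m)_dB` is fit by the shifted difference of the
#' Lorentzian confocal model,
#' `10 log10 h(i; z0, zR) - 10 log10 h(i+m; z0, zR)`, by least squares on
#' the dB residuals. The objective is non-convex, so a multi-start search is
#' used: `z0` over a uniform grid on `[0, zmax]` and `zR` over a log-spaced
#' grid on `[pitch, zmax]`, each start refined by Nelder-Mead.
#'
#' @param y dB data vector of length `p - m` (built exactly as in
#'   [build_design()], with fall-off removed beforehand if available).
#' @param grid The [acquisition_grid()] the scans were sampled on.
#' @param m Pixel shift between the two scans (>= 1).
#' @param n_starts Starts per parameter axis (default 16 x 16).
#' @return An object of class `confocal_fit`: `z0_hat` and `zR_hat` (mm),
#'   `residual` (dB per fitted position), `fit_rmse` (dB), `g_lin`
#'   (normalized confocal envelope on the full grid), `converged`, and
#'   `identifiable` (FALSE when the data are flat so any focus fits).
#' @export
fit_confocal_ratio <- function(y, grid, m, n_starts = 16L) {
  stopifnot(inherits(grid, "oct_grid"), m >= 1, m < grid$p)
  m <- as.integer(m)
  n <- grid$p - m
  stopifnot(length(y) == n)
  z <- grid$z
  model_diff <- function(z0, zR) {
    H <- -10 * log10(((z - z0) / zR)^2 + 1)
    H[seq_len(n)] - H[m + seq_len(n)]
  }
  obj <- function(par) {
    r <- y - model_diff(par[1], exp(par[2]))
    mean(r^2)
  }
  z0_grid <- seq(0, grid$zmax, length.out = n_starts)
  zR_grid <- exp(seq(log(grid$pitch), log(grid$zmax), length.out = n_starts))
  best <- NULL
  converged <- FALSE
  for (a in z0_grid) for (b in zR_grid) {
    o <- stats::optim(c(a, log(b)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) {
      best <- o
      converged <- o$convergence == 0
    }
  }
  # polish: restarted simplexes escape the collapsed-simplex plateau of a
  # single Nelder-Mead run and take the optimum to machine level
  for (r in 1:4) {
    o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-16))
    if (o$value < best$value) best <- o else break
  }
  z0_hat <- best$par[1]
  zR_hat <- max(exp(best$par[2]), grid$pitch)
  residual <- y - model_diff(z0_hat, zR_hat)
  h <- confocal_function(grid, z0_hat, zR_hat)
  identifiable <- stats::sd(y) > .Machine$double.eps^0.5
  if (!converged)
    warning("confocal ratio fit did not converge; best-found parameters returned")
  structure(
    list(z0_hat = z0_hat, zR_hat = zR_hat, residual = residual,
         fit_rmse = sqrt(mean(residual^2)),
         g_lin = h / max(h), g_db = to_db(h / max(h)),
         converged = converged, identifiable = identifiable,
         m = m, grid = grid),
    class = "confocal_fit"
  )
}

#' Remove a measured fall-off curve from a B-scan
#'
#' Elementwise division of a linear-intensity scan by a per-depth fall-off
#' curve, used before the confocal-only ratio fit when the system fall-off
#' has been measured separately.
#'
#' @param bscan Linear-intensity matrix (depth x lateral) or vector.
#' @param falloff_curve Strictly positive numeric vector, one value per
#'   depth pixel.
#' @return Scan with the fall-off divided out.
#' @export
remove_falloff <- function(bscan, falloff_curve) {
  p <- if (is.matrix(bscan)) nrow(bscan) else length(bscan)
  stopifnot(length(falloff_curve) == p, all(falloff_curve > 0))
  if (is.matrix(bscan)) bscan / falloff_curve else bscan / falloff_curve
}

#' Combine a fitted confocal envelope with a fall-off curve
#'
#' Builds the full `g` estimate of the ratio-fit method: the fitted
#' confocal envelope multiplied by the measured fall-off curve (identity
#' when no curve is available), normalized to maximum one.
#'
#' @param fit A [fit_confocal_ratio()] result.
#' @param falloff_curve Optional per-depth fall-off values (strictly
#'   positive, length `p`).
#' @return A `g_estimate` (method `"ratio"`).
#' @export
combine_with_falloff <- function(fit, falloff_curve = NULL) {
  stopifnot(inherits(fit, "confocal_fit"))
  h <- confocal_function(fit$grid, fit$z0_hat, fit$zR_hat)
  g <- if (is.null(falloff_curve)) h else {
    stopifnot(length(falloff_curve) == fit$grid$p, all(falloff_curve > 0))
    h * falloff_curve
  }
  g <- g / max(g)
  structure(
    list(method = "ratio", coefficients = c(z0 = fit$z0_hat, zR = fit$zR_hat),
         g_db = to_db(g), g_lin = g, normalization = "max-one",
         n_basis = 2L, p = fit$grid$p, mapping = NA_character_,
         residual = fit$residual, fit_rmse = fit$fit_rmse,
         cond = NA_real_, ill_conditioned = NA, shifts = c(0L, fit$m)),
    class = "g_estimate"
  )
}

#' Ratio-fit baseline end-to-end
#'
#' Laterally averages a pair of vertically shifted scans, optionally divides
#' out a measured fall-off curve, fits the two-parameter confocal model to
#' the dB ratio data and returns the resulting `g` estimate (confocal fit
#' times fall-off curve) for downstream correction.
#'
#' @param scans An `oct_pair` or a list of two linear B-scans / A-scans.
#' @param grid The [acquisition_grid()] (taken from the `oct_pair` when one
#'   is supplied).
#' @param m Pixel shift (taken from the `oct_pair` when one is supplied).
#' @param falloff_curve Optional measured fall-off, removed before the fit
#'   and re-multiplied into the returned estimate.
#' @param n_starts Multi-start density, see [fit_confocal_ratio()].
#' @return A `g_estimate` (method `"ratio"`) with the confocal parameters in
#'   `$coefficients`.
#' @export
ratio_fit <- function(scans, grid = NULL, m = NULL, falloff_curve = NULL,
                      n_starts = 16L) {
  if (inherits(scans, "oct_pair")) {
    grid <- scans$grid
    m <- scans$shifts[2] - scans$shifts[1]
    scans <- scans$scans[1:2]
  }
  stopifnot(inherits(grid, "oct_grid"), length(scans) == 2, !is.null(m))
  avg <- lapply(scans, lateral_average)
  if (!is.null(falloff_curve))
    avg <- lapply(avg, remove_falloff, falloff_curve = falloff_curve)
  db <- lapply(avg, to_db)
  n <- grid$p - m
  y <- db[[1]][seq_len(n)] - db[[2]][m + seq_len(n)]
  fit <- fit_confocal_ratio(y, grid, m, n_starts)
  combine_with_falloff(fit, falloff_curve)
}
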