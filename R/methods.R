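#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a combined-function estimate
#'
#' @param x A `g_estimate`.
#' @param grid Optional [acquisition_grid()]; adds a `depth_mm` column.
#' @param ... Unused.
#' @return Tibble with one row per depth pixel: `pixel`, `g_db`, `g_lin`
#'   (and `depth_mm` when a grid is given).
#' @export
tidy.g_estimate <- function(x, grid = NULL, ...) {
  out <- tibble::tibble(pixel = seq_len(x$p), g_db = x$g_db, g_lin = x$g_lin)
  if (!is.null(grid)) out$depth_mm <- depth_of(grid, out$pixel)
  out
}

#' One-row summary of a combined-function estimate
#'
#' @param x A `g_estimate`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_basis`, `fit_rmse`, `cond`,
#'   `ill_conditioned`, `normalization`.
#' @export
glance.g_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_basis = x$n_basis, fit_rmse = x$fit_rmse,
    cond = x$cond, ill_conditioned = x$ill_conditioned,
    normalization = x$normalization
  )
}

#' @export
print.g_estimate <- function(x, ...) {
  cat(sprintf("<g_estimate> %s fit, %d depth pixels\n", x$method, x$p))
  if (x$method == "basis") {
    cat(sprintf("  basis functions solved: %d   cond(B) = %.4g%s\n",
                x$n_basis, x$cond,
                if (isTRUE(x$ill_conditioned)) "  [ILL-CONDITIONED]" else ""))
  } else {
    cat(sprintf("  confocal parameters: z0 = %.4f mm, zR = %.4f mm\n",
                x$coefficients["z0"], x$coefficients["zR"]))
  }
  cat(sprintf("  fit RMSE: %.4g dB   normalization: %s\n",
              x$fit_rmse, x$normalization))
  invisible(x)
}

#' Plot a combined-function estimate
#'
#' @param object A `g_estimate`.
#' @param grid Optional [acquisition_grid()] for a depth (mm) axis.
#' @param scale `"db"` or `"linear"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.g_estimate <- function(object, grid = NULL,
                                scale = c("db", "linear"), ...) {
  scale <- match.arg(scale)
  df <- tidy(object, grid = grid)
  xvar <- if (is.null(grid)) "pixel" else "depth_mm"
  yvar <- if (scale == "db") "g_db" else "g_lin"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]])) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (is.null(grid)) "depth pixel" else "depth (mm)",
      y = if (scale == "db") "10 log10 g (dB)" else "g (linear)",
      title = sprintf("Combined confocal x fall-off estimate (%s fit)",
                      object$method)
    )
}

#' @export
tidy.confocal_fit <- function(x, ...) {
  tibble::tibble(term = c("z0", "zR"),
                 estimate = c(x$z0_hat, x$zR_hat),
                 unit = "mm")
}

#' @export
glance.confocal_fit <- function(x, ...) {
  tibble::tibble(z0_hat = x$z0_hat, zR_hat = x$zR_hat,
                 fit_rmse = x$fit_rmse, converged = x$converged,
                 identifiable = x$identifiable)
}

#' @export
print.confocal_fit <- function(x, ...) {
  cat(sprintf("<confocal_fit> z0 = %.4f mm, zR = %.4f mm, RMSE = %.4g dB\n",
              x$z0_hat, x$zR_hat, x$fit_rmse))
  if (!x$identifiable)
    cat("  note: data are flat; parameters are not identifiable\n")
  invisible(x)
}

#' @export
tidy.ac_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, window_start = min(x$window),
                 window_end = max(x$window),
                 refractive_index = x$refractive_index,
                 r_squared = x$r_squared)
}

#' @export
print.ac_fit <- function(x, ...) {
  cat(sprintf("<ac_fit> mu = %.4f mm^-1 (pixels %d-%d, n = %.2f)\n",
              x$mu, min(x$window), max(x$window), x$refractive_index))
  invisible(x)
}

#' @export
tidy.correction_report <- function(x, ...) {
  tibble::tibble(
    quantity = c("rmse_uncorrected", "rmse_corrected"),
    value_db = c(x$rmse_uncorrected, x$rmse_corrected),
    overlap_pixels = x$overlap
  )
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("<correction_report> overlap %d px: RMSE %.4g dB -> %.4g dB\n",
              x$overlap, x$rmse_uncorrected, x$rmse_corrected))
  invisible(x)
}

#' Plot per-lateral-position RMSE of a correction
#'
#' @param object A `correction_report` computed from full B-scans.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correction_report <- function(object, ...) {
  if (is.null(object$per_lateral_rmse))
    stop("per-lateral RMSE unavailable (report was built from A-scan vectors)")
  df <- tibble::tibble(lateral = seq_along(object$per_lateral_rmse),
                       rmse_db = object$per_lateral_rmse)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lateral, y = .data$rmse_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lateral position (pixel)",
                  y = "corrected RMSE (dB)",
                  title = "Corrected-scan similarity per lateral position")
}

#' @export
print.oct_design <- function(x, ...) {
  cat(sprintf("<oct_design> %d basis rows x %d columns, cond = %.4g\n",
              nrow(x$B), ncol(x$B), x$cond))
  invisible(x)
}

#' @export
print.oct_pair <- function(x, ...) {
  cat(sprintf("<oct_pair> %d scan(s) of %d x %d, shifts: %s, seed %d\n",
              length(x$scans), x$grid$p, ncol(x$scans[[1]]),
              paste(x$shifts, collapse = "/"), x$noise$seed))
  invisible(x)
}

#' @importFrom rlang .data
NULL
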