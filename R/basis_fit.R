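#' Build the Chebyshev difference design system
#'
#' For every pair of scans `(j, k)` with relative shift `m = shifts[k] -
#' shifts[j]`, the data block is `y(i) = S_j(i) - S_k(i + m)` (dB) for
#' `i = 1 .. p - m`, and the model block has rows
#' `beta_r(i) - beta_r(i + m)`, `r = 2 .. N + 1`. Blocks from all pairs (and,
#' optionally, all lateral columns) are concatenated column-wise. The
#' condition number of the concatenated matrix is the ratio of its largest
#' to smallest singular value.
#'
#' @param basis A [chebyshev_basis()] sampled on the full grid `1..p`.
#' @param scans_db List of two or more dB-scale A-scans (numeric vectors of
#'   length `p`) or B-scans (`p x L` dB matrices; all must share `L`).
#' @param shifts Integer pixel offsets of each scan relative to the first;
#'   `shifts[1] == 0`, strictly increasing, so every pairwise shift is >= 1.
#' @param lateral For matrix input: `"ybar"` (default) averages the
#'   per-column data vectors pixel-wise before fitting, `"columns"`
#'   concatenates one data/model block per column. The two give identical
#'   coefficients because the model block is column-independent.
#' @return An object of class `oct_design`: list with `y` (data vector),
#'   `B` (`N` x `length(y)` matrix), `cond`, `N`, `p`, and a `pairs` tibble
#'   of bookkeeping (scan indices, shift, block length).
#' @export
build_design <- function(basis, scans_db, shifts,
                         lateral = c("ybar", "columns")) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(basis, "cheb_basis"), is.list(scans_db),
            length(scans_db) >= 2, length(shifts) == length(scans_db))
  shifts <- as.integer(shifts)
  if (shifts[1] != 0) stop("shifts[1] must be 0 (first scan is the reference)")
  if (any(diff(shifts) <= 0))
    stop("shifts must be strictly increasing; a zero pairwise shift is degenerate")
  p <- basis$p
  ok <- vapply(scans_db, function(s)
    (if (is.matrix(s)) nrow(s) else length(s)) == p, logical(1))
  if (!all(ok)) stop("every scan must have ", p, " depth pixels")
  V <- basis$values
  combos <- utils::combn(length(scans_db), 2)
  y_all <- list(); B_all <- list(); book <- list()
  for (q in seq_len(ncol(combos))) {
    j <- combos[1, q]; k <- combos[2, q]
    m <- shifts[k] - shifts[j]
    if (m >= p) stop("pairwise shift ", m, " exceeds the grid")
    n <- p - m
    Bblk <- V[-1, seq_len(n), drop = FALSE] -
            V[-1, m + seq_len(n), drop = FALSE]
    sj <- scans_db[[j]]; sk <- scans_db[[k]]
    if (is.matrix(sj)) {
      ycols <- sj[seq_len(n), , drop = FALSE] -
               sk[m + seq_len(n), , drop = FALSE]
      if (lateral == "ybar") {
        y_all[[q]] <- rowMeans(ycols)
        B_all[[q]] <- Bblk
      } else {
        y_all[[q]] <- as.numeric(ycols)
        B_all[[q]] <- Bblk[, rep(seq_len(n), ncol(ycols)), drop = FALSE]
      }
    } else {
      y_all[[q]] <- sj[seq_len(n)] - sk[m + seq_len(n)]
      B_all[[q]] <- Bblk
    }
    book[[q]] <- tibble::tibble(scan_a = j, scan_b = k, shift = m,
                                n_columns = length(y_all[[q]]))
  }
  y <- unlist(y_all, use.names = FALSE)
  B <- do.call(cbind, B_all)
  d <- svd(B, nu = 0, nv = 0)$d
  structure(
    list(y = y, B = B, cond = max(d) / min(d), N = basis$N, p = p,
         basis = basis, pairs = do.call(rbind, book)),
    class = "oct_design"
  )
}

#' Solve the design system by pseudo-inverse
#'
#' Computes `c = y B^+` with an SVD-based pseudo-inverse (relative
#' singular-value cutoff at machine precision, no regularization), the
#' residual `eps = y - c B` and its RMSE. If the condition number exceeds
#' `cond_threshold` an ill-conditioning warning is raised but the solution
#' is still returned.
#'
#' @param design An [build_design()] result.
#' @param cond_threshold Conditioning threshold for the warning
#'   (default 6.7e8, the double-precision rule of thumb).
#' @return List with `c` (length-`N` coefficients for `beta_2..beta_{N+1}`),
#'   `residual`, `fit_rmse`, `cond` and `ill_conditioned`.
#' @export
solve_coefficients <- function(design, cond_threshold = 6.7e8) {
  stopifnot(inherits(design, "oct_design"))
  B <- design$B; y <- design$y
  s <- svd(B)
  tol <- max(s$d) * max(dim(B)) * .Machine$double.eps
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  # c (1 x N) = y (1 x M) V diag(dinv) U'
  cvec <- as.numeric(((y %*% s$v) * rep(dinv, each = 1)) %*% t(s$u))
  residual <- y - as.numeric(cvec %*% B)
  ill <- design$cond > cond_threshold
  if (ill)
    warning(sprintf(paste0("design matrix is ill-conditioned (cond = %.4g > ",
                           "%.2g); reduce N or add scans at more depths"),
                    design$cond, cond_threshold))
  list(c = cvec, residual = residual,
       fit_rmse = sqrt(mean(residual^2)),
       cond = design$cond, ill_conditioned = ill)
}

#' Assemble the estimated combined function from coefficients
#'
#' `10 log10 ghat(i) = sum_k c_k beta_k(i)` plus a normalization constant:
#' `"max-one"` shifts the dB curve so its maximum is 0 (ghat max 1),
#' `"air-min-one"` rescales so the minimum over the supplied air pixels is
#' 1, `"none"` leaves the raw span (the overall scale is unidentifiable
#' from shifted-scan ratios).
#'
#' @param coefficients Numeric vector of length `N` (coefficients of
#'   `beta_2 .. beta_{N+1}` in the dB domain).
#' @param basis The [chebyshev_basis()] the coefficients refer to.
#' @param normalization `"max-one"` (default), `"air-min-one"` or `"none"`.
#' @param air_rows Depth pixels treated as air (required for
#'   `"air-min-one"`).
#' @return An object of class `g_estimate` (see [basis_fit()]); fit
#'   diagnostics are `NA` when assembling from bare coefficients.
#' @export
assemble_g <- function(coefficients, basis,
                       normalization = c("max-one", "air-min-one", "none"),
                       air_rows = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(basis, "cheb_basis"),
            length(coefficients) == basis$N)
  g_db <- as.numeric(coefficients %*% basis$values[-1, , drop = FALSE])
  if (normalization == "max-one") {
    g_db <- g_db - max(g_db)
  } else if (normalization == "air-min-one") {
    if (is.null(air_rows)) stop("air_rows required for air-min-one")
    g_db <- g_db - min(g_db[air_rows])
  }
  structure(
    list(method = "basis", coefficients = coefficients, g_db = g_db,
         g_lin = from_db(g_db), normalization = normalization,
         n_basis = basis$N, p = basis$p, mapping = basis$mapping,
         residual = NULL, fit_rmse = NA_real_, cond = NA_real_,
         ill_conditioned = NA),
    class = "g_estimate"
  )
}

# normalize scan input (oct_pair / list of matrices or vectors) to a list of
# laterally averaged dB A-scans plus shifts and p
scans_to_db <- function(scans, shifts = NULL) {
  if (inherits(scans, "oct_pair")) {
    shifts <- scans$shifts
    scans <- scans$scans
  }
  if (!is.list(scans)) stop("scans must be a list of vectors/matrices or an oct_pair")
  if (is.null(shifts)) stop("shifts must be supplied")
  avg <- lapply(scans, lateral_average)
  list(db = lapply(avg, to_db), shifts = as.integer(shifts),
       p = length(avg[[1]]))
}

#' Extract the combined confocal and fall-off function (basis fit)
#'
#' End-to-end estimation of `g(z)` from two or more vertically shifted
#' scans: the scans are laterally averaged in linear intensity, converted to
#' dB, the difference system over every pair of depths is assembled,
#' solved by SVD least squares, and the estimate assembled and normalized.
#'
#' @param scans An `oct_pair` from [build_bscan_pair()], or a list of
#'   linear-intensity B-scan matrices / A-scan vectors.
#' @param N Number of basis coefficients to solve for.
#' @param shifts Pixel offsets of each scan (taken from the `oct_pair` when
#'   one is supplied).
#' @param normalization Passed to [assemble_g()].
#' @param air_rows Air pixels for `"air-min-one"` normalization.
#' @param mapping Basis mapping, see [chebyshev_basis()].
#' @param cond_threshold Ill-conditioning warning threshold.
#' @return An object of class `g_estimate`: the per-pixel estimate in dB
#'   (`g_db`) and linear (`g_lin`) scale, the coefficients, the fit residual
#'   and its RMSE (dB), the design condition number and the
#'   ill-conditioning flag. Use [generics::tidy()] / [generics::glance()]
#'   for tibble views and `autoplot()` to display the curve.
#' @examples
#' pair <- simulate_model_scene(n_lateral = 1)
#' fit <- basis_fit(pair, N = 20)
#' glance(fit)
#' @export
basis_fit <- function(scans, N, shifts = NULL,
                      normalization = c("max-one", "air-min-one", "none"),
                      air_rows = NULL,
                      mapping = c("endpoints", "cell"),
                      cond_threshold = 6.7e8) {
  normalization <- match.arg(normalization)
  mapping <- match.arg(mapping)
  inp <- scans_to_db(scans, shifts)
  basis <- chebyshev_basis(N, inp$p, mapping)
  design <- build_design(basis, inp$db, inp$shifts)
  sol <- solve_coefficients(design, cond_threshold)
  est <- assemble_g(sol$c, basis, normalization, air_rows)
  est$residual <- sol$residual
  est$fit_rmse <- sol$fit_rmse
  est$cond <- sol$cond
  est$ill_conditioned <- sol$ill_conditioned
  est$shifts <- inp$shifts
  est
}

#' Laterally resolved basis fit with a moving window
#'
#' Slides an odd-width window of lateral A-scans across a pair of B-scans
#' and extracts one `g` estimate per window, assigned to the window center.
#' Columns left of the first center reuse the first window's estimate;
#' columns right of the last reuse the last one.
#'
#' @param scan1,scan2 Linear-intensity B-scans (`p x L` matrices) with
#'   `scan2` shifted `m` pixels deeper.
#' @param m Pixel shift between the scans (>= 1).
#' @param N Number of basis coefficients.
#' @param window Odd window width in lateral pixels, `<= L`.
#' @param ... Passed to [basis_fit()].
#' @return An object of class `g_estimate_lateral`: list with `g_db` and
#'   `g_lin` (`p x L` matrices, one column per lateral position), `centers`
#'   (window-center column of each fitted window) and `fits` (list of
#'   `g_estimate`s, one per window).
#' @export
basis_fit_moving_window <- function(scan1, scan2, m, N, window, ...) {
  stopifnot(is.matrix(scan1), is.matrix(scan2),
            identical(dim(scan1), dim(scan2)))
  L <- ncol(scan1)
  window <- as.integer(window)
  if (window > L) stop("window larger than the B-scan width")
  if (window %% 2L == 0L) stop("window must be odd")
  hw <- (window - 1L) %/% 2L
  centers <- (hw + 1L):(L - hw)
  fits <- lapply(centers, function(ctr) {
    cols <- (ctr - hw):(ctr + hw)
    basis_fit(list(scan1[, cols, drop = FALSE],
                   scan2[, cols, drop = FALSE]),
              N = N, shifts = c(0L, m), ...)
  })
  which_fit <- pmin(pmax(seq_len(L), centers[1]), centers[length(centers)]) -
    centers[1] + 1L
  g_db <- vapply(which_fit, function(i) fits[[i]]$g_db,
                 numeric(nrow(scan1)))
  structure(
    list(g_db = g_db, g_lin = from_db(g_db), centers = centers,
         window = window, fits = fits),
    class = "g_estimate_lateral"
  )
}

#' Conditioning report for a design system
#'
#' @param design An [build_design()] result.
#' @param threshold Condition-number threshold separating well- from
#'   ill-conditioned systems.
#' @return List with `cond`, `ill_conditioned`, `N`, `n_columns` and
#'   `remedies` (suggestions when ill-conditioned: fewer basis functions or
#'   more vertically shifted scans).
#' @export
check_conditioning <- function(design, threshold = 6.7e8) {
  stopifnot(inherits(design, "oct_design"))
  ill <- design$cond > threshold
  list(
    cond = design$cond,
    ill_conditioned = ill,
    threshold = threshold,
    N = design$N,
    n_columns = length(design$y),
    remedies = if (ill)
      c("reduce the number of basis functions N",
        "add vertically shifted scans at additional depths")
    else character(0)
  )
}
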