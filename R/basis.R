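#' Sampled Chebyshev basis on the pixel grid
#'
#' Chebyshev polynomials of the first kind, `beta_1 = 1`, `beta_2 = x`,
#' `beta_k = 2 x beta_{k-1} - beta_{k-2}`, sampled at each depth pixel after
#' mapping the pixel index to `x` in `[-1, 1]`. The default mapping places
#' the grid endpoints at -1 and +1: `x_i = -1 + 2 (i - 1) / (p - 1)`. An
#' alternative cell-based mapping `x_i = 2 i / p - 1` is selectable; the two
#' differ in the conditioning of the difference design matrix.
#'
#' @param N Number of solved coefficients; `N + 1` polynomials
#'   (`beta_1 .. beta_{N+1}`) are sampled. `N >= 1`.
#' @param p Grid length in pixels; must satisfy `p >= N + 2`.
#' @param mapping Pixel-to-`[-1, 1]` rule, `"endpoints"` (default) or
#'   `"cell"`.
#' @return An object of class `cheb_basis`: list with `N`, `p`, `x` (mapped
#'   abscissae) and `values`, an `(N + 1) x p` matrix with row `k` holding
#'   `beta_k(i)`.
#' @examples
#' b <- chebyshev_basis(5, 64)
#' all(b$values[1, ] == 1)
#' @export
chebyshev_basis <- function(N, p, mapping = c("endpoints", "cell")) {
  mapping <- match.arg(mapping)
  N <- as.integer(N); p <- as.integer(p)
  if (N < 1) stop("N must be at least 1")
  if (p < N + 2L) stop("grid too short: need p >= N + 2")
  x <- if (mapping == "endpoints") -1 + 2 * (seq_len(p) - 1) / (p - 1)
       else 2 * seq_len(p) / p - 1
  V <- matrix(0, N + 1L, p)
  V[1L, ] <- 1
  V[2L, ] <- x
  if (N + 1L >= 3L)
    for (k in 3L:(N + 1L)) V[k, ] <- 2 * x * V[k - 1L, ] - V[k - 2L, ]
  structure(list(N = N, p = p, x = x, mapping = mapping, values = V),
            class = "cheb_basis")
}
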