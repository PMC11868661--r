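#' Ideal single-scattering A-scan
#'
#' Noise-free, envelope-free depth profile of backscattered intensity under
#' the single-scattering Beer-Lambert model:
#' `A(z) = k alpha beta L0 mu(z) exp(-2 int_0^z mu(s) ds)`.
#' The cumulative attenuation integral is evaluated in closed form per layer
#' (mu is piecewise constant), so the profile is exact at every pixel.
#'
#' @param phantom A [layered_phantom()]; boundaries must lie within the grid.
#' @param grid An [acquisition_grid()].
#' @param det [detection_params()].
#' @return Numeric vector of length `grid$p`, linear intensity; zero in air.
#' @examples
#' grid <- acquisition_grid(512, 2.5)
#' ph <- layered_phantom(c(0.073, 0.561, 1.050, 2.5), c(1, 2, 4))
#' a <- ideal_ascan(ph, grid, detection_params())
#' @export
ideal_ascan <- function(phantom, grid, det = detection_params()) {
  stopifnot(inherits(phantom, "oct_phantom"), inherits(grid, "oct_grid"),
            inherits(det, "oct_detection"))
  b <- phantom$boundaries
  if (min(b) < 0 || max(b) > grid$zmax)
    stop("phantom boundaries must lie within [0, zmax] of the grid")
  scale <- det$k * det$alpha * det$beta * det$L0
  scale * mu_at(phantom, grid$z) * exp(-2 * cumulative_mu(phantom, grid$z))
}

#' Shift a depth profile deeper by m pixels
#'
#' Models moving the sample away from the zero-delay line: the profile moves
#' down by `m` pixels, newly exposed shallow pixels take the air value (0)
#' and pixels pushed beyond the grid are discarded.
#'
#' @param profile Numeric vector (or depth x lateral matrix; each column is
#'   shifted).
#' @param m Shift in pixels, `0 <= m < length(profile)`.
#' @return Shifted profile of the same length/shape.
#' @export
vertical_shift <- function(profile, m) {
  m <- as.integer(m)
  p <- if (is.matrix(profile)) nrow(profile) else length(profile)
  if (m < 0 || m >= p) stop("shift m must satisfy 0 <= m < p")
  if (m == 0L) return(profile)
  if (is.matrix(profile)) {
    rbind(matrix(0, m, ncol(profile)), profile[seq_len(p - m), , drop = FALSE])
  } else {
    c(numeric(m), profile[seq_len(p - m)])
  }
}

#' Confocal sensitivity envelope
#'
#' `h(z) = 1 / (((z - z0)/zR)^2 + 1)`: the Lorentzian axial sensitivity of a
#' focused Gaussian beam, peaking at the focal plane `z0` with half-maximum
#' at `z0 +- zR`.
#'
#' @param grid An [acquisition_grid()] (evaluated at its pixel depths), or a
#'   numeric vector of depths in mm.
#' @param z0 Focal plane depth, mm.
#' @param zR Apparent Rayleigh range, mm (> 0).
#' @return Values in (0, 1].
#' @export
confocal_function <- function(grid, z0, zR) {
  stopifnot(zR > 0)
  z <- if (inherits(grid, "oct_grid")) grid$z else as.numeric(grid)
  1 / (((z - z0) / zR)^2 + 1)
}

#' Spectrometer sensitivity fall-off envelope
#'
#' `f(z) = sinc(zeta)^2 exp(-w^2 zeta^2 / (2 ln 2))` with
#' `zeta = (pi/2) z / zRD`, `zRD = lambda0^2/(4 dlambda)` the maximum ranging
#' depth and `w = deltalambda/dlambda` the normalized spectral resolution.
#' `sinc` is unnormalized (`sin(x)/x`).
#'
#' @inheritParams confocal_function
#' @param lambda0 Central wavelength, m.
#' @param dlambda Wavelength spacing per spectrometer pixel, m.
#' @param deltalambda Spectral resolution FWHM, m.
#' @return Values in (0, 1], equal to 1 at z = 0.
#' @export
falloff_function <- function(grid, lambda0 = 1310e-9, dlambda = 7.1875e-11,
                             deltalambda = 1.1055e-10) {
  stopifnot(lambda0 > 0, dlambda > 0, deltalambda > 0)
  z <- if (inherits(grid, "oct_grid")) grid$z else as.numeric(grid)
  zRD <- lambda0^2 / (4 * dlambda) * 1e3  # mm
  w <- deltalambda / dlambda
  zeta <- (pi / 2) * (z / zRD)
  s <- ifelse(zeta == 0, 1, sin(zeta) / zeta)
  s^2 * exp(-w^2 * zeta^2 / (2 * log(2)))
}

#' Combined system response on a grid
#'
#' The product of the confocal envelope (with any configured perturbation)
#' and, if enabled, the fall-off envelope.
#'
#' @param system A [system_response()].
#' @param grid An [acquisition_grid()].
#' @return Numeric vector of length `grid$p`, strictly positive.
#' @export
combined_response <- function(system, grid) {
  stopifnot(inherits(system, "oct_system"), inherits(grid, "oct_grid"))
  g <- confocal_function(grid, system$z0, system$zR)
  if (!is.null(system$confocal_mod)) g <- g * system$confocal_mod(grid$z)
  if (system$falloff)
    g <- g * falloff_function(grid, system$lambda0, system$dlambda,
                              system$deltalambda)
  g
}

#' Clamp a linear-intensity profile at a dB floor
#'
#' Applies the signal lower limit: values below `floor_db` (relative to the
#' profile maximum) are raised to that level.
#'
#' @param x Linear intensity vector or matrix with at least one positive
#'   value.
#' @param floor_db Floor in dB relative to `max(x)` (negative).
#' @return Clamped profile.
#' @export
apply_signal_floor <- function(x, floor_db = -30) {
  mx <- max(x)
  if (mx <= 0) return(x)
  pmax(x, mx * 10^(floor_db / 10))
}

# sqrt of grid-wide mean ideal intensity, the amplitude scale entering sigma
noise_amplitude_scale <- function(phantom, grid, det) {
  sqrt(mean(det$k * det$alpha * det$beta * det$L0 * mu_at(phantom, grid$z)))
}

#' Add speckle and shot noise to an amplitude profile
#'
#' Operates in the amplitude domain (square root of intensity). Speckle
#' multiplies the intensity by the exponential factor
#' `n_sp = -(4/pi) ln(u)` (mean `4/pi`), i.e. the amplitude by its square
#' root -- the convention that reproduces the speckle-limited corrected-scan
#' RMSE of the layered-phantom benchmark. Shot noise is additive on the
#' amplitude, `sigma * (-(4/pi) ln(u') - 4/pi)` with
#' `sigma = C * 10^(-snr_db/20)`. Both noise generators can be replaced via
#' `speckle_fn` / `shot_fn` (functions of the draw count returning the
#' intensity factors / amplitude terms), reflecting that the exact
#' inverse-transform expressions are a modelling choice.
#'
#' Draws come from the current RNG state; seed control belongs to the caller
#' (see [build_bscan_pair()]).
#'
#' @param amplitude Numeric vector, amplitude-domain profile.
#' @param spec A [noise_spec()].
#' @param C Amplitude scale entering sigma; typically
#'   `sqrt(mean(k alpha beta L0 mu(z)))` over the full grid.
#' @param speckle_fn,shot_fn Optional replacement noise generators.
#' @return Noisy amplitude profile, same length.
#' @export
add_noise <- function(amplitude, spec, C,
                      speckle_fn = NULL, shot_fn = NULL) {
  stopifnot(inherits(spec, "oct_noise"))
  n <- length(amplitude)
  out <- amplitude
  if (spec$speckle) {
    nsp <- if (is.null(speckle_fn)) -(4 / pi) * log(stats::runif(n))
           else speckle_fn(n)
    out <- out * sqrt(nsp)
  }
  if (spec$shot) {
    sigma <- C * 10^(-spec$snr_db / 20)
    nsh <- if (is.null(shot_fn))
      sigma * (-(4 / pi) * log(stats::runif(n)) - 4 / pi)
    else shot_fn(n) * sigma
    out <- out + nsh
  }
  out
}

#' Simulate a set of vertically shifted B-scans with known ground truth
#'
#' Builds the measured scans of the layered-phantom experiment: the ideal
#' A-scan is clamped at the dB floor, vertically shifted per scan, converted
#' to amplitude, given independent speckle/shot noise per pixel, lateral
#' position and scan, squared back to intensity, and multiplied by the
#' combined confocal x fall-off envelope.
#'
#' @param phantom A [layered_phantom()].
#' @param grid An [acquisition_grid()].
#' @param det [detection_params()].
#' @param system [system_response()].
#' @param noise [noise_spec()]; set `speckle = FALSE, shot = FALSE` for a
#'   noise-free pair. The RNG seed is taken from `noise$seed`.
#' @param shifts Integer pixel offsets of each scan relative to the first;
#'   must start at 0 and be strictly increasing.
#' @param n_lateral Number of lateral A-scans per B-scan.
#' @return An object of class `oct_pair`: list with `scans` (list of
#'   depth x lateral linear-intensity matrices), `shifts`, `truth_g`
#'   (ground-truth combined response), `truth_ideal` (floored noise-free
#'   profiles per scan), `grid`, `phantom`, `det`, `system`, `noise`.
#' @examples
#' pair <- build_bscan_pair(
#'   layered_phantom(c(0.073, 0.561, 1.050, 2.5), c(1, 2, 4)),
#'   acquisition_grid(512, 2.5), detection_params(), system_response(),
#'   noise_spec(speckle = FALSE, shot = FALSE), shifts = c(0L, 50L),
#'   n_lateral = 1)
#' @export
build_bscan_pair <- function(phantom, grid, det = detection_params(),
                             system = system_response(),
                             noise = noise_spec(),
                             shifts = c(0L, 50L), n_lateral = 200L) {
  stopifnot(n_lateral >= 1, length(shifts) >= 2,
            shifts[1] == 0, all(diff(shifts) >= 0), max(shifts) < grid$p)
  shifts <- as.integer(shifts)
  g <- combined_response(system, grid)
  a1 <- ideal_ascan(phantom, grid, det)
  ideal <- lapply(shifts, function(m)
    apply_signal_floor(vertical_shift(a1, m), noise$floor_db))
  C <- noise_amplitude_scale(phantom, grid, det)
  any_noise <- noise$speckle || noise$shot
  if (any_noise) set.seed(noise$seed)
  scans <- lapply(ideal, function(prof) {
    amp <- sqrt(prof)
    cols <- vapply(seq_len(n_lateral), function(j) {
      a <- if (any_noise) add_noise(amp, noise, C) else amp
      g * a^2
    }, numeric(grid$p))
    matrix(cols, nrow = grid$p)
  })
  structure(
    list(scans = scans, shifts = shifts, truth_g = g,
         truth_ideal = ideal, truth_mu = phantom$mu,
         grid = grid, phantom = phantom, det = det,
         system = system, noise = noise),
    class = "oct_pair"
  )
}

#' The three-layer model phantom scene
#'
#' Convenience constructor for the base simulated experiment: a 512-pixel,
#' 2.5 mm A-scan of a three-layer sample (1, 2 and 4 mm^-1 between
#' boundaries at 0.073, 0.561, 1.050 and 2.5 mm), confocal focus at
#' 0.7324 mm with a 0.3662 mm Rayleigh range, Telesto-like fall-off, a
#' 50-pixel vertical shift and 200 lateral A-scans.
#'
#' @param noise A [noise_spec()]; default noise-free.
#' @param shifts Pixel offsets of the scans (default `c(0, 50)`).
#' @param n_lateral Lateral A-scans per B-scan.
#' @param system Optional [system_response()] override.
#' @return An `oct_pair` (see [build_bscan_pair()]).
#' @export
simulate_model_scene <- function(noise = noise_spec(speckle = FALSE,
                                                    shot = FALSE),
                                 shifts = c(0L, 50L), n_lateral = 200L,
                                 system = system_response()) {
  build_bscan_pair(
    phantom = layered_phantom(c(0.073, 0.561, 1.050, 2.5), c(1, 2, 4)),
    grid = acquisition_grid(512L, 2.5),
    det = detection_params(),
    system = system,
    noise = noise,
    shifts = shifts,
    n_lateral = n_lateral
  )
}
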