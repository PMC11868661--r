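#' Axial acquisition grid
#'
#' Defines the depth sampling of an A-scan: `p` pixels covering `(0, zmax]`
#' with pixel `i` at depth `z_i = i * zmax / p`. This is the affine
#' pixel-to-depth rule consistent with the usual convention that pixel `p`
#' sits at the maximum imaging depth (e.g. on a 512-pixel, 2.5 mm grid,
#' pixel 150 is at 0.7324 mm and a 50-pixel shift is 0.2441 mm).
#'
#' @param p Number of depth pixels per A-scan (integer, >= 2).
#' @param zmax Maximum imaging depth in mm (> 0).
#' @return An object of class `oct_grid` with fields `p`, `zmax`,
#'   `pitch` (mm per pixel) and `z` (depth of each pixel, mm).
#' @examples
#' g <- acquisition_grid(512, 2.5)
#' g$z[150]  # 0.7324 mm
#' @export
acquisition_grid <- function(p = 512L, zmax = 2.5) {
  p <- as.integer(p)
  stopifnot(length(p) == 1L, p >= 2L, length(zmax) == 1L, zmax > 0)
  structure(
    list(p = p, zmax = zmax, pitch = zmax / p, z = seq_len(p) * zmax / p),
    class = "oct_grid"
  )
}

#' Depth of a pixel index
#'
#' @param grid An [acquisition_grid()].
#' @param i Pixel index (1-based), may be a vector.
#' @return Depth(s) in mm.
#' @export
depth_of <- function(grid, i) {
  stopifnot(inherits(grid, "oct_grid"), all(i >= 1), all(i <= grid$p))
  i * grid$zmax / grid$p
}

#' Layered attenuation phantom
#'
#' A sample made of homogeneous layers, each with a constant attenuation
#' coefficient. Depths above the first boundary are air (mu = 0).
#'
#' @param boundaries Strictly increasing depths in mm: the air/sample surface
#'   followed by each interface, ending at the bottom of the last layer.
#'   Length must be `length(mu) + 1`.
#' @param mu Attenuation coefficient per layer, mm^-1 (>= 0).
#' @param refractive_index Refractive index of the medium, used when
#'   converting optical depth to physical depth for attenuation reporting.
#' @return An object of class `oct_phantom`.
#' @examples
#' ph <- layered_phantom(c(0.073, 0.561, 1.050, 2.5), c(1, 2, 4))
#' @export
layered_phantom <- function(boundaries, mu, refractive_index = 1) {
  stopifnot(length(boundaries) == length(mu) + 1L,
            all(diff(boundaries) > 0), all(mu >= 0),
            refractive_index > 0)
  structure(
    list(boundaries = as.numeric(boundaries), mu = as.numeric(mu),
         refractive_index = refractive_index),
    class = "oct_phantom"
  )
}

#' Attenuation coefficient profile of a phantom
#'
#' @param phantom An [layered_phantom()].
#' @param z Depths in mm.
#' @return mu(z) in mm^-1; 0 in air and below the last boundary.
#' @export
mu_at <- function(phantom, z) {
  stopifnot(inherits(phantom, "oct_phantom"))
  b <- phantom$boundaries
  idx <- findInterval(z, b, left.open = FALSE)
  out <- numeric(length(z))
  inside <- idx >= 1L & idx <= length(phantom$mu)
  # z exactly at the bottom boundary belongs to the last layer
  at_bottom <- z == b[length(b)]
  out[inside] <- phantom$mu[idx[inside]]
  out[at_bottom] <- phantom$mu[length(phantom$mu)]
  out
}

# exact cumulative integral of piecewise-constant mu from 0 to z (mm^-1 * mm)
cumulative_mu <- function(phantom, z) {
  b <- phantom$boundaries
  mu <- phantom$mu
  vapply(z, function(q) {
    s <- 0
    for (l in seq_along(mu)) {
      if (q > b[l]) s <- s + mu[l] * (min(q, b[l + 1L]) - b[l])
    }
    s
  }, numeric(1))
}

#' Detection/measurement scaling parameters
#'
#' Scalars of the single-scattering measurement model: the ideal intensity
#' profile is `k * alpha * beta * L0 * mu(z) * exp(-2 int_0^z mu)`.
#'
#' @param k Measurement scaling factor (unitless, > 0).
#' @param alpha Backscattered fraction (0 < alpha <= 1).
#' @param beta Detector quantum efficiency (0 < beta <= 1).
#' @param L0 Source intensity, mW/mm^2 (> 0).
#' @return An object of class `oct_detection`.
#' @export
detection_params <- function(k = 1000, alpha = 0.75, beta = 0.75, L0 = 5) {
  stopifnot(k > 0, alpha > 0, alpha <= 1, beta > 0, beta <= 1, L0 > 0)
  structure(list(k = k, alpha = alpha, beta = beta, L0 = L0),
            class = "oct_detection")
}

#' System depth-response specification
#'
#' Parameters of the confocal envelope `h(z) = 1 / (((z - z0)/zR)^2 + 1)` and
#' the spectrometer sensitivity fall-off
#' `f(z) = sinc(zeta)^2 * exp(-w^2 zeta^2 / (2 ln 2))` with
#' `zeta = (pi/2) z / zRD`, `zRD = lambda0^2 / (4 dlambda)` and
#' `w = deltalambda / dlambda`. The sinc is unnormalized,
#' `sinc(x) = sin(x)/x`, the standard spectral-domain roll-off form.
#'
#' @param z0 Focal plane depth, mm.
#' @param zR Apparent Rayleigh range, mm (> 0).
#' @param lambda0 Central wavelength, m.
#' @param dlambda Wavelength spacing per spectrometer pixel, m.
#' @param deltalambda Spectral resolution FWHM, m.
#' @param confocal_mod Optional function of depth (mm) returning a
#'   multiplicative perturbation of the confocal envelope; `NULL` = identity.
#' @param falloff Logical; include the fall-off envelope in the combined
#'   response (`FALSE` models an ideal spectrometer).
#' @return An object of class `oct_system` with derived fields `zRD` (mm)
#'   and `w`.
#' @examples
#' sys <- system_response()  # Telesto-like defaults
#' sys$zRD  # 5.9690 mm
#' @export
system_response <- function(z0 = 0.7324, zR = 0.3662,
                            lambda0 = 1310e-9, dlambda = 7.1875e-11,
                            deltalambda = 1.1055e-10,
                            confocal_mod = NULL, falloff = TRUE) {
  stopifnot(zR > 0, lambda0 > 0, dlambda > 0, deltalambda > 0,
            is.null(confocal_mod) || is.function(confocal_mod))
  structure(
    list(z0 = z0, zR = zR, lambda0 = lambda0, dlambda = dlambda,
         deltalambda = deltalambda,
         zRD = lambda0^2 / (4 * dlambda) * 1e3,  # mm
         w = deltalambda / dlambda,
         confocal_mod = confocal_mod, falloff = isTRUE(falloff)),
    class = "oct_system"
  )
}

#' Noise specification for simulated scans
#'
#' Speckle multiplies the signal intensity by
#' `n_sp = -(4/pi) ln(u)` (mean `4/pi`); shot noise is additive zero-mean
#' on the amplitude,
#' `n_sh = sigma * (-(4/pi) ln(u) - 4/pi)` with
#' `sigma = C * 10^(-SNR/20)`, where `C` is the square root of the grid-wide
#' mean ideal intensity. Both draws use independent uniform variates per
#' pixel, per lateral position and per scan.
#'
#' @param snr_db Signal-to-noise ratio in dB.
#' @param speckle Logical; apply multiplicative speckle noise.
#' @param shot Logical; apply additive shot noise.
#' @param floor_db Signal lower limit in dB relative to the profile maximum,
#'   applied to the noise-free intensity before noise injection.
#' @param seed Integer RNG seed driving all noise draws.
#' @return An object of class `oct_noise`.
#' @export
noise_spec <- function(snr_db = 80, speckle = TRUE, shot = TRUE,
                       floor_db = -30, seed = 1L) {
  stopifnot(is.finite(snr_db), is.finite(floor_db))
  structure(
    list(snr_db = snr_db, speckle = isTRUE(speckle), shot = isTRUE(shot),
         floor_db = floor_db, seed = as.integer(seed)),
    class = "oct_noise"
  )
}
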