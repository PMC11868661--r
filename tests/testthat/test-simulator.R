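test_that("ideal A-scan follows the single-scattering model exactly", {
  grid <- model_grid()
  ph <- model_phantom()
  det <- detection_params()
  a <- ideal_ascan(ph, grid, det)

  expect_length(a, grid$p)
  # air above the surface carries no backscatter
  expect_true(all(a[grid$z < 0.073] == 0))

  # agrees with an independent cumulative-integral oracle at every pixel
  scale <- det$k * det$alpha * det$beta * det$L0
  oracle <- scale * mu_at(ph, grid$z) * exp(-2 * oracle_cum_mu(ph, grid$z))
  expect_equal(a, oracle, tolerance = 1e-12)

  # first in-tissue pixel: kabL0 * mu * exp(-2 mu eps) with eps the
  # penetration past the surface
  i0 <- which(a > 0)[1]
  eps <- grid$z[i0] - 0.073
  expect_equal(a[i0], scale * 1 * exp(-2 * 1 * eps), tolerance = 1e-12)

  # log-slope inside each homogeneous layer equals -2 mu
  for (l in 1:3) {
    idx <- layer_interior(ph, grid, l)
    slope <- unname(coef(lm(log(a[idx]) ~ grid$z[idx]))[2])
    expect_equal(slope, -2 * ph$mu[l], tolerance = 1e-9)
  }

  # no scatterers -> identically zero profile
  empty <- layered_phantom(c(0.1, 2.0), 0)
  expect_true(all(ideal_ascan(empty, grid, det) == 0))

  # boundaries outside the grid are rejected
  expect_error(ideal_ascan(layered_phantom(c(0.1, 3.0), 1), grid, det),
               "within")
})

test_that("vertical shift moves the sample deeper and is invertible on the overlap", {
  grid <- model_grid()
  a <- ideal_ascan(model_phantom(), grid)

  expect_identical(vertical_shift(a, 0), a)

  s <- vertical_shift(a, 50)
  # surface boundary moves from pixel 15 to pixel 65
  expect_identical(which(a > 0)[1], 15L)
  expect_identical(which(s > 0)[1], 65L)
  # newly exposed shallow pixels take the air value
  expect_true(all(s[1:50] == 0))
  # shift then unshift recovers the original over the overlap
  expect_equal(s[51:512], a[1:462])

  expect_error(vertical_shift(a, -1), "shift")
  expect_error(vertical_shift(a, 512), "shift")

  # matrix input shifts every column
  m <- cbind(a, 2 * a)
  sm <- vertical_shift(m, 10)
  expect_equal(sm[, 2], vertical_shift(2 * a, 10))
})

test_that("confocal envelope is a unit-peak Lorentzian in depth", {
  grid <- model_grid()
  h <- confocal_function(grid, 0.7324, 0.3662)
  expect_true(all(h > 0 & h <= 1))
  expect_equal(which.max(h), which.min(abs(grid$z - 0.7324)))
  # evaluated at the focus and at one Rayleigh range off it
  expect_equal(confocal_function(c(0.7324, 0.7324 + 0.3662, 0.7324 - 0.3662),
                                 0.7324, 0.3662),
               c(1, 0.5, 0.5))
  # z0/zR = 2 puts the zero-depth sensitivity at exactly 0.2
  expect_equal(confocal_function(0, 0.7324, 0.3662), 0.2)
  expect_error(confocal_function(grid, 0.7, -1))
})

test_that("fall-off envelope has the spectrometer-derived scale and decays", {
  sys <- system_response()
  expect_equal(sys$zRD, 1310e-9^2 / (4 * 7.1875e-11) * 1e3, tolerance = 1e-12)
  expect_equal(sys$zRD, 5.9690, tolerance = 1e-4)
  expect_equal(sys$w, 1.1055e-10 / 7.1875e-11, tolerance = 1e-12)
  expect_equal(sys$w, 1.53809, tolerance = 1e-5)

  grid <- model_grid()
  f <- falloff_function(grid)
  expect_equal(falloff_function(0), 1)
  expect_true(all(diff(f) < 0))

  # value at full depth pinned by an independent scalar evaluation
  # (unnormalized sinc convention)
  zeta <- (pi / 2) * (2.5 / sys$zRD)
  f_ref <- (sin(zeta) / zeta)^2 * exp(-sys$w^2 * zeta^2 / (2 * log(2)))
  expect_equal(f[grid$p], f_ref, tolerance = 1e-12)
})

test_that("noise model has the documented moments and switches off cleanly", {
  spec_off <- noise_spec(speckle = FALSE, shot = FALSE)
  a <- c(1, 2, 3)
  expect_identical(add_noise(a, spec_off, C = 1), a)

  # speckle multiplies the intensity by a factor of mean 4/pi
  # (E[-ln u] = 1); on unit amplitude the squared output exposes it
  set.seed(7)
  n <- 1e6
  ones <- rep(1, n)
  sp <- add_noise(ones, noise_spec(speckle = TRUE, shot = FALSE), C = 1)
  expect_equal(mean(sp^2), 4 / pi, tolerance = 5e-3)

  # shot term is zero-mean with sd proportional to sigma = C 10^(-SNR/20)
  set.seed(8)
  sh <- add_noise(rep(0, n), noise_spec(snr_db = 80, speckle = FALSE,
                                        shot = TRUE), C = 1)
  sigma <- 1e-4
  expect_lt(abs(mean(sh)), 5 * sigma / sqrt(n))
  expect_equal(sd(sh), sigma * 4 / pi, tolerance = 0.01)
})

test_that("signal floor clamps at the stated level relative to the maximum", {
  x <- c(1000, 1, 0)
  fx <- apply_signal_floor(x, -30)
  expect_equal(fx, c(1000, 1, 1))
  expect_equal(min(to_db(fx / max(fx))), -30)
})

test_that("simulated scan sets are reproducible, laterally independent and truth-tagged", {
  noise <- noise_spec(snr_db = 80, seed = 11)
  p1 <- simulate_model_scene(noise = noise, n_lateral = 4)
  p2 <- simulate_model_scene(noise = noise, n_lateral = 4)
  expect_identical(p1$scans, p2$scans)
  # different lateral columns carry different noise realizations
  expect_false(identical(p1$scans[[1]][, 1], p1$scans[[1]][, 2]))
  # different seed, different draws
  p3 <- simulate_model_scene(noise = noise_spec(snr_db = 80, seed = 12),
                             n_lateral = 4)
  expect_false(identical(p1$scans[[1]], p3$scans[[1]]))

  # ground truth is the confocal x fall-off product
  clean <- model_scene_clean()
  grid <- clean$grid
  expect_equal(clean$truth_g,
               confocal_function(grid, 0.7324, 0.3662) *
                 falloff_function(grid),
               tolerance = 1e-14)

  # noise off: every A-scan is exactly g times the floored ideal profile
  expect_equal(clean$scans[[1]][, 1],
               clean$truth_g * clean$truth_ideal[[1]], tolerance = 1e-14)
  expect_equal(clean$scans[[2]][, 1],
               clean$truth_g * clean$truth_ideal[[2]], tolerance = 1e-14)

  # a zero shift duplicates the scan (degenerate but well-defined)
  same <- simulate_model_scene(shifts = c(0L, 0L), n_lateral = 1)
  expect_identical(same$scans[[1]], same$scans[[2]])

  # fall-off disabled and no perturbation: truth is the bare confocal curve
  nofall <- simulate_model_scene(system = system_response(falloff = FALSE),
                                 n_lateral = 1)
  expect_equal(nofall$truth_g, confocal_function(grid, 0.7324, 0.3662),
               tolerance = 1e-14)

  # a confocal perturbation multiplies into the truth
  mod <- function(z) 1 + 0.1 * z
  pm <- simulate_model_scene(system = system_response(confocal_mod = mod),
                             n_lateral = 1)
  expect_equal(pm$truth_g,
               confocal_function(grid, 0.7324, 0.3662) * mod(grid$z) *
                 falloff_function(grid),
               tolerance = 1e-14)
})
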