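test_that("confocal parameters are recovered exactly from confocal-only data", {
  grid <- model_grid()
  m <- 50L
  n <- grid$p - m
  h <- confocal_function(grid, 0.7324, 0.3662)
  H <- to_db(h)
  y <- H[1:n] - H[(1 + m):grid$p]
  fit <- fit_confocal_ratio(y, grid, m)

  expect_equal(fit$z0_hat, 0.7324, tolerance = 1e-6)
  expect_equal(fit$zR_hat, 0.3662, tolerance = 1e-6)
  expect_lt(fit$fit_rmse, 1e-9)
  expect_true(fit$identifiable)
})

test_that("flat ratio data are reported as non-identifiable", {
  grid <- acquisition_grid(128L, 1.0)
  fit <- fit_confocal_ratio(numeric(128 - 10), grid, 10L)
  expect_false(fit$identifiable)
  expect_lt(fit$fit_rmse, 1e-9)
})

test_that("fall-off removal divides out the curve and is invertible", {
  grid <- model_grid()
  f <- falloff_function(grid)
  set.seed(4)
  img <- matrix(abs(rnorm(grid$p * 3, 5)), grid$p, 3)
  expect_identical(remove_falloff(img, rep(1, grid$p)), img)
  expect_equal(remove_falloff(img, f) * f, img, tolerance = 1e-12)
  expect_error(remove_falloff(img, f[-1]))
  expect_error(remove_falloff(img, -f))
})

test_that("removing the true fall-off lets the confocal-only fit recover the focus", {
  pair <- model_scene_clean()
  f <- falloff_function(pair$grid)
  est <- ratio_fit(list(pair$scans[[1]], pair$scans[[2]]),
                   grid = pair$grid, m = 50L, falloff_curve = f)
  expect_equal(unname(est$coefficients["z0"]), 0.7324, tolerance = 1e-3)
  expect_equal(unname(est$coefficients["zR"]), 0.3662, tolerance = 1e-3)
  # the recombined estimate matches the true combined envelope
  expect_equal(est$g_lin, pair$truth_g / max(pair$truth_g), tolerance = 1e-4)
})

test_that("combining a perfect confocal fit with the true fall-off yields the truth", {
  pair <- model_scene_clean()
  grid <- pair$grid
  m <- 50L
  n <- grid$p - m
  h <- confocal_function(grid, 0.7324, 0.3662)
  H <- to_db(h)
  y <- H[1:n] - H[(1 + m):grid$p]
  fit <- fit_confocal_ratio(y, grid, m)

  g_plain <- combine_with_falloff(fit)
  expect_equal(max(g_plain$g_lin), 1)
  expect_equal(g_plain$g_lin, h / max(h), tolerance = 1e-5)

  f <- falloff_function(grid)
  g_full <- combine_with_falloff(fit, f)
  expect_equal(g_full$g_lin, pair$truth_g / max(pair$truth_g),
               tolerance = 1e-5)
})

test_that("a moderately sized basis model fits better than the confocal baseline", {
  # the two model families are not nested, so superiority is not guaranteed
  # at very small N (a handful of low-order polynomials cannot express the
  # log-Lorentzian); from N = 10 on, the flexible model wins on every
  # scenario exercised here
  pair <- model_scene_clean()
  rf <- ratio_fit(pair)
  for (N in c(10, 15, 20)) {
    bf <- basis_fit(pair, N = N)
    expect_lte(bf$fit_rmse, rf$fit_rmse + 1e-12)
  }

  # also under a perturbed confocal shape (model mismatch for the baseline)
  pert <- simulate_model_scene(
    system = system_response(falloff = FALSE,
                             confocal_mod = function(z) 1 + 0.3 * sin(2 * z)),
    n_lateral = 1)
  expect_lte(basis_fit(pert, N = 10)$fit_rmse, ratio_fit(pert)$fit_rmse)
})
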