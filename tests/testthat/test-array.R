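test_that("grid specification validates geometry", {
  g <- array_grid_spec(3, 4, unit_radius = 5, pitch = 14)
  expect_equal(nrow(g$unit_centers), 12)
  expect_error(array_grid_spec(2, 2, unit_radius = 8, pitch = 10), "overlap")
  bad_centers <- rbind(c(10, 10), c(12, 12), c(40, 40), c(60, 60))
  expect_error(array_grid_spec(2, 2, unit_radius = 5, unit_centers = bad_centers),
               "overlap")
})

test_that("synthetic array round-trips through unit measurement", {
  g <- array_grid_spec(3, 3, unit_radius = 8, pitch = 24, background_gray = 4)
  img <- synth_array_image(g, unit_gray = 16)
  expect_true(all(img %in% c(4, 16)))

  rep <- measure_units(img, g)
  expect_true(all(abs(rep$per_unit_agl - 16) < 1e-12))
  expect_equal(rep$overall_agl, 16)
  expect_equal(rep$overall_si, 0)

  # disk pixel count close to the analytic area
  expect_lt(max(abs(rep$n_pixels - pi * 8^2)) / (pi * 8^2), 0.12)

  # per-unit grays in row-major order
  img2 <- synth_array_image(g, unit_gray = seq(10, 90, by = 10))
  rep2 <- measure_units(img2, g)
  expect_equal(rep2$per_unit_agl, matrix(seq(10, 90, by = 10), 3, 3, byrow = TRUE))

  # overall AGL equals the pixel-weighted mean of unit AGLs
  expect_equal(rep2$overall_agl,
               sum(t(rep2$per_unit_agl) * rep2$n_pixels) / sum(rep2$n_pixels))

  # unit outside image is a configuration error
  expect_error(measure_units(img[1:30, ], g), "outside")
})

test_that("restore_units recovers unit grays from a speckled array", {
  g <- array_grid_spec(2, 2, unit_radius = 24, pitch = 60, background_gray = 8)
  clean <- synth_array_image(g, unit_gray = 16)
  noisy <- add_speckle(clean, speckle_spec(0.25, seed = 77))
  res <- restore_units(noisy, g)
  expect_true(all(abs(res$report$per_unit_agl - 16) <= 1))
  expect_lt(abs(res$report$overall_agl - 16), 0.6)
  # zero-noise round trip is exact
  res0 <- restore_units(clean, g)
  expect_equal(res0$report$per_unit_agl, matrix(16, 2, 2))
})

test_that("fit_line matches the normal-equations oracle and trivial lines", {
  f1 <- fit_line(1:10, 1:10)
  expect_equal(f1$slope, 1); expect_equal(f1$intercept, 0); expect_equal(f1$r2, 1)

  f2 <- fit_line(0:5, 2 * (0:5) + 1)
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 1); expect_equal(f2$r2, 1)

  set.seed(170)
  x <- runif(40, 0, 10); y <- 3.2 * x - 4 + rnorm(40)
  got <- fit_line(x, y); want <- ref_fit_line(x, y)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$r2, want$r2, tolerance = 1e-10)
  expect_error(fit_line(rep(1, 5), 1:5), "degenerate")
})

test_that("gray-to-index inverts the calibration line", {
  calib <- fit_line(c(0, 0.01, 0.02, 0.03), c(0.4, 10.2, 20.1, 29.9))
  expect_equal(gray_to_index(calib$intercept, calib), 0)
  dn <- 0.017
  dg <- calib$intercept + calib$slope * dn
  expect_equal(gray_to_index(dg, calib), dn, tolerance = 1e-12)

  # parameter recovery: bias vanishes as noise does
  set.seed(180)
  x <- seq(0, 0.05, length.out = 30)
  for (sdn in c(1, 0.01)) {
    y <- 1000 * x + 0.5 + rnorm(30, sd = sdn)
    f <- fit_line(x, y)
    expect_lt(abs(f$slope - 1000), 40 * sdn + 1e-6)
  }
})
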