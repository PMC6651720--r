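test_that("multiplicative speckle has the required moments and limits", {
  img <- constant_image(40, c(64, 64))

  # vanishing variance: output equals input after quantization
  tiny <- add_speckle(img, speckle_spec(1e-10, seed = 1))
  expect_identical(tiny, img)

  # mean preservation without censoring: E[M(1+n)] = M, checked against a
  # large Monte-Carlo draw at the highest variance
  sp <- speckle_spec(1.0, clip = FALSE, quantize = FALSE, seed = 42)
  big <- constant_image(40, c(1024, 1024))
  noisy <- add_speckle(big, sp)
  se <- 40 * sqrt(1.0) / sqrt(length(big))
  expect_lt(abs(mean(noisy) - 40), 3 * se)

  # uniform family support: no sample outside M * (1 +/- sqrt(3v))
  a <- sqrt(3 * 1.0)
  expect_gte(min(noisy), 40 * (1 - a))
  expect_lte(max(noisy), 40 * (1 + a))

  # determinism: same seed, bit-identical realizations
  s1 <- add_speckle(img, speckle_spec(0.5, seed = 7))
  s2 <- add_speckle(img, speckle_spec(0.5, seed = 7))
  expect_identical(s1, s2)

  # parameter validation
  expect_error(speckle_spec(0), "variance")
  expect_error(add_speckle(matrix(c(1, NA, 2, 3), 2), speckle_spec(0.5)),
               "non-finite")
})

test_that("gaussian and exponential families are zero-mean with the set variance", {
  for (fam in c("gaussian", "exponential")) {
    sp <- speckle_spec(0.25, family = fam, clip = FALSE, quantize = FALSE, seed = 3)
    noisy <- add_speckle(constant_image(100, c(512, 512)), sp)
    n <- noisy / 100 - 1
    expect_lt(abs(mean(n)), 4 * sqrt(0.25 / length(n)))
    expect_lt(abs(sd(n) - 0.5), 0.01)
  }
})

test_that("speckle intensity densities match their closed forms and normalize", {
  # single pattern: exponential density
  expect_equal(intensity_pdf_single(0, Ibar = 2), 0.5)
  expect_equal(intensity_pdf_single(-1, Ibar = 5), 0)
  expect_equal(integrate(intensity_pdf_single, 0, Inf, Ibar = 3)$value,
               1, tolerance = 1e-6)

  # N-pattern sum: closed form, normalization, N = 1 reduction, mode
  I <- seq(0, 30, by = 0.37)
  for (N in c(1, 2, 5, 10)) {
    closed <- ifelse(I >= 0, I^(N - 1) / (gamma(N) * 2^N) * exp(-I / 2), 0)
    expect_equal(intensity_pdf_sum(I, N = N, I0 = 2), closed, tolerance = 1e-12)
    expect_equal(integrate(intensity_pdf_sum, 0, Inf, N = N, I0 = 2)$value,
                 1, tolerance = 1e-6)
    # mode at (N-1) I0 (quadrature-free check via derivative sign change)
    if (N > 1) {
      m <- (N - 1) * 2
      expect_gt(intensity_pdf_sum(m, N, 2), intensity_pdf_sum(m - 0.1, N, 2))
      expect_gt(intensity_pdf_sum(m, N, 2), intensity_pdf_sum(m + 0.1, N, 2))
    }
  }
  expect_equal(intensity_pdf_sum(I, N = 1, I0 = 2),
               intensity_pdf_single(I, Ibar = 2), tolerance = 1e-12)
  expect_error(intensity_pdf_single(1, Ibar = 0), "Ibar")
  expect_error(intensity_pdf_sum(1, N = 0, I0 = 1), "N")
})

test_that("singular-pixel fraction follows the uniform-support analysis", {
  img <- constant_image(40, c(256, 256))

  expect_equal(singular_fraction(img, img), 0)

  # below variance 1/3 the multiplier support stays under 2: no singulars
  sp <- speckle_spec(0.33, clip = FALSE, quantize = FALSE, seed = 9)
  expect_equal(singular_fraction(add_speckle(img, sp), img), 0)

  # at variance 1 the closed form is P(n > 1) = (sqrt(3) - 1) / (2 sqrt(3))
  sp1 <- speckle_spec(1.0, clip = FALSE, quantize = FALSE, seed = 10)
  fr <- singular_fraction(add_speckle(img, sp1), img)
  p <- (sqrt(3) - 1) / (2 * sqrt(3))
  expect_lt(abs(fr - p), 4 * sqrt(p * (1 - p) / length(img)))

  expect_error(singular_fraction(img, constant_image(40, c(8, 8))), "dimensions")
})

test_that("clipped quantized ensembles show the AGL rise with variance", {
  img <- constant_image(40, c(128, 128))
  agl <- vapply(c(0.4, 0.6, 0.8, 1.0), function(v) {
    mean(vapply(1:8, function(k)
      average_gray(add_speckle(img, speckle_spec(v, seed = 100L * k + round(100 * v)))),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(agl) > 0))
  expect_gt(agl[4], 42)   # censoring at zero inflates the mean markedly at v = 1
})
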