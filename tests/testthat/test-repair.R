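test_that("9x9 smoothing preserves constants, normalization and the mean", {
  cst <- constant_image(77, c(20, 20))
  expect_equal(smooth_image(cst), cst, tolerance = 1e-12)

  # unit impulse: response sums to 1 (kernel normalization)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  expect_equal(sum(smooth_image(imp)), 1, tolerance = 1e-12)

  # global mean preserved exactly under mirror padding + symmetric kernel
  for (s in 1:3) {
    x <- rand_image(17, seed = 80 + s)
    expect_equal(mean(smooth_image(x)), mean(x), tolerance = 1e-6)
    expect_equal(mean(smooth_image(x, type = "box")), mean(x), tolerance = 1e-6)
  }
  expect_error(smooth_image(rand_image(5), size = 4), "odd")
})

test_that("gradient field matches the ramp closed form and the oracle", {
  gf0 <- gradient_field(constant_image(3, c(10, 10)))
  expect_true(all(gf0$magnitude == 0) && all(gf0$theta == 0))

  # ramp S(x, y) = x (row index)
  ramp <- matrix(rep(1:12, 12), 12, 12)
  gf <- gradient_field(ramp)
  inside <- 2:11
  expect_true(all(gf$gx[inside, inside] == 2))
  expect_true(all(gf$gy[inside, inside] == 0))
  expect_true(all(gf$g45[inside, inside] == -2))
  expect_true(all(gf$g135[inside, inside] == 2))
  expect_equal(gf$magnitude[5, 5], sqrt(12))

  for (s in 1:3) {
    x <- rand_image(9, seed = 90 + s)
    got <- gradient_field(x)
    want <- ref_gradient(x)
    expect_equal(got$gx, want$gx, tolerance = 1e-12)
    expect_equal(got$g45, want$g45, tolerance = 1e-12)
    expect_equal(got$g135, want$g135, tolerance = 1e-12)
    expect_equal(got$magnitude, want$magnitude, tolerance = 1e-12)
  }
})

test_that("marking is empty on constants and catches an isolated spike", {
  m0 <- mark_residual(gradient_field(constant_image(40, c(16, 16))))
  expect_equal(attr(m0, "n_marked"), 0L)

  spiked <- constant_image(40, c(21, 21)); spiked[11, 11] <- 140
  m <- mark_residual(gradient_field(smooth_image(spiked)), mark_policy(k = 2, min_grad = 1))
  expect_gt(attr(m, "n_marked"), 0)
  # the marked region surrounds the spike
  w <- which(m, arr.ind = TRUE)
  expect_true(all(abs(w[, 1] - 11) <= 6 & all(abs(w[, 2] - 11) <= 6)))
})

test_that("median repair touches only masked pixels and matches the sort oracle", {
  x <- rand_image(15, seed = 101)
  none <- matrix(FALSE, 15, 15)
  expect_identical(median_repair(x, none), x)

  spiked <- constant_image(40, c(15, 15)); spiked[8, 8] <- 255
  only <- none; only[8, 8] <- TRUE
  rep1 <- median_repair(spiked, only, 9L)
  expect_equal(rep1[8, 8], 40)
  expect_identical(rep1[-8, ], spiked[-8, ])

  for (s in 1:3) {
    set.seed(110 + s)
    mask <- matrix(runif(225) < 0.3, 15)
    y <- rand_image(15, seed = 120 + s)
    expect_equal(median_repair(y, mask, 5L), ref_masked_median(y, mask, 5L),
                 tolerance = 1e-12)
  }
  expect_error(median_repair(x, none, 8L), "odd")
})

test_that("pnlm_g is a near-fixed point on clean images and restores ensembles", {
  cst0 <- constant_image(40, c(64, 64))
  fit0 <- pnlm_g(cst0)
  expect_lt(abs(average_gray(fit0$image) - 40), 0.05)
  expect_true(fit0$converged)
  cst <- constant_image(40, c(256, 256))

  # restored ensemble at two variances: exact gray recovery, tiny SI,
  # dynamic range never widened, marks non-increasing over passes
  for (v in c(0.3, 0.8)) {
    noisy <- add_speckle(cst, speckle_spec(v, seed = 300 + round(10 * v)))
    fit <- pnlm_g(noisy)
    expect_lt(abs(average_gray(fit$image) - 40), 0.05)
    expect_lte(speckle_index(fit$image), 0.02)
    expect_gte(min(fit$image), min(noisy))
    expect_lte(max(fit$image), max(noisy))
    expect_true(all(diff(fit$marks) <= 0))
  }
})

test_that("pnlm_g preserves structure on non-homogeneous scenes", {
  # two-level scene: global consolidation must not engage
  scene <- constant_image(8, c(80, 80)); scene[20:60, 20:60] <- 60
  noisy <- add_speckle(scene, speckle_spec(0.1, seed = 5))
  fit <- pnlm_g(noisy)
  expect_false(fit$global_pass)
  inner <- fit$image[30:50, 30:50]
  outer <- fit$image[1:10, 1:10]
  expect_gt(mean(inner), 50)
  expect_lt(mean(outer), 15)
})
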