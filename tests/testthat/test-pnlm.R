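test_that("ROAD statistic matches forced cases and the brute-force oracle", {
  expect_true(all(road_statistic(constant_image(40, c(8, 8))) == 0))

  # center 100 surrounded by 40s: the 4 smallest deviations are four 60s
  img <- constant_image(40, c(5, 5)); img[3, 3] <- 100
  expect_equal(road_statistic(img)[3, 3], 240)

  for (s in 1:4) {
    x <- rand_image(7, seed = s)
    expect_equal(road_statistic(x, pnlm_params(road_radius = 1, road_L = 4)),
                 ref_road(x, 1, 4), tolerance = 1e-10)
  }
  x <- rand_image(9, seed = 9)
  expect_equal(road_statistic(x, pnlm_params(road_radius = 2, road_L = 6)),
               ref_road(x, 2, 6), tolerance = 1e-10)
  expect_error(pnlm_params(road_L = 9), "road_L")
})

test_that("undamaged probability is exp(-alpha ROAD), monotone decreasing", {
  expect_equal(undamaged_probability(matrix(0, 2, 2)), matrix(1, 2, 2))
  expect_equal(undamaged_probability(matrix(240, 1, 1), 0.01)[1, 1],
               exp(-2.4))
  r <- matrix(seq(0, 500, length.out = 25), 5)
  p <- undamaged_probability(r)
  expect_true(all(diff(as.vector(p)[order(as.vector(r))]) < 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(undamaged_probability(matrix(-1, 2, 2)), "negative")
})

test_that("probability-weighted patch distance reduces and matches the oracle", {
  x <- rand_image(9, seed = 21)
  P1 <- matrix(1, 9, 9)
  # identical patches -> 0
  expect_equal(prob_patch_distance(x, P1, c(4, 4), c(4, 4), 2), 0)

  # all probabilities 1 -> classical mean-squared patch distance
  i <- c(4, 4); j <- c(6, 5); f <- 2
  d_classical <- mean((x[(i[1]-f):(i[1]+f), (i[2]-f):(i[2]+f)] -
                       x[(j[1]-f):(j[1]+f), (j[2]-f):(j[2]+f)])^2)
  expect_equal(prob_patch_distance(x, P1, i, j, f), d_classical, tolerance = 1e-12)

  # random probabilities against the literal summation oracle
  set.seed(31)
  P <- matrix(runif(81, 0.05, 1), 9)
  U <- ref_pad(x, f); Q <- ref_pad(P, f)
  expect_equal(prob_patch_distance(x, P, i, j, f),
               ref_patch_dist(U, Q, i + f, j + f, f), tolerance = 1e-12)
})

test_that("pnlm_denoise equals the literal brute-force restoration", {
  for (s in 1:2) {
    x <- rand_image(16, seed = 40 + s)
    par <- pnlm_params(search_radius = 3, patch_radius = 1, h = 60)
    P <- undamaged_probability(road_statistic(x, par), par$alpha)
    expect_equal(pnlm_denoise(x, par), ref_pnlm(x, P, 3, 1, 60),
                 tolerance = 1e-8)
  }
  # larger geometry once
  x <- rand_image(20, seed = 50)
  par <- pnlm_params(search_radius = 5, patch_radius = 2, h = 120)
  P <- undamaged_probability(road_statistic(x, par), par$alpha)
  expect_equal(pnlm_denoise(x, par), ref_pnlm(x, P, 5, 2, 120), tolerance = 1e-8)
})

test_that("with all probabilities 1 the filter is classical non-local means", {
  x <- rand_image(14, seed = 61)
  par <- pnlm_params(search_radius = 3, patch_radius = 1, h = 80)
  P1 <- matrix(1, 14, 14)
  expect_equal(pnlm_denoise(x, par, P = P1), ref_pnlm(x, P1, 3, 1, 80),
               tolerance = 1e-8)
})

test_that("restoration is a convex combination: bounded by the window range", {
  for (s in 1:3) {
    x <- rand_image(18, seed = 70 + s)
    y <- pnlm_denoise(x, pnlm_params(h = 50))
    expect_true(all(y >= min(x) - 1e-9) && all(y <= max(x) + 1e-9))
    expect_true(all(is.finite(y)))
  }
  # constant image is a fixed point
  cst <- constant_image(123, c(12, 12))
  expect_equal(pnlm_denoise(cst, pnlm_params(h = 10)), cst, tolerance = 1e-9)
})

test_that("a damaged (high-ROAD) pixel influences the restoration less", {
  x <- constant_image(40, c(11, 11))
  x[6, 6] <- 255                      # impulse
  par <- pnlm_params(search_radius = 3, patch_radius = 1, h = 40)
  with_p <- pnlm_denoise(x, par)
  without_p <- pnlm_denoise(x, par, P = matrix(1, 11, 11))
  # neighbors of the impulse are pulled towards 255 less when the impulse
  # carries a low undamaged probability
  expect_lt(with_p[6, 5], without_p[6, 5])
  expect_lt(abs(with_p[6, 5] - 40), abs(without_p[6, 5] - 40))
})

test_that("whole-image search mode is the exact flat-kernel limit", {
  x <- rand_image(12, seed = 91)
  par_inf <- pnlm_params(search_radius = Inf)
  P <- undamaged_probability(road_statistic(x, par_inf), 0.01)
  out <- pnlm_denoise(x, par_inf)
  expect_true(all(out == out[1, 1]))
  expect_equal(out[1, 1], sum(P * x) / sum(P), tolerance = 1e-12)
})
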