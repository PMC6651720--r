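#' Parameters of the probability-based non-local means filter
#'
#' @param search_radius Search-window radius r; the filter averages over the
#'   (2r+1) x (2r+1) window around each pixel.  Default 5.  `Inf` selects the
#'   whole-image search window of the non-local means formulation; in that
#'   limit the patch kernel is taken flat (every weight 1) and the filter is
#'   the exact probability-weighted global mean, computed in O(n).
#' @param patch_radius Patch radius f; similarity is measured between
#'   (2f+1) x (2f+1) patches.  Must satisfy `search_radius > patch_radius >= 1`.
#' @param road_radius Radius of the ROAD neighborhood (default 1, i.e. the
#'   8-connected neighbors).
#' @param road_L Number of smallest absolute deviations summed in the ROAD
#'   statistic; default 4, must be at most the neighborhood size minus one.
#' @param alpha Probability scale: the undamaged probability of a pixel is
#'   `exp(-alpha * ROAD)`; default 0.01.
#' @param h Weight-kernel bandwidth (gray levels).  `NULL` (default) selects
#'   `10 * sigma_hat` per image, where `sigma_hat` is a robust noise-level
#'   estimate from the median absolute Laplacian residual (see
#'   [estimate_noise_sd()]), floored at 0.1.
#' @return An object of class `"pnlm_params"`.
#' @export
pnlm_params <- function(search_radius = 5L, patch_radius = 2L,
                        road_radius = 1L, road_L = 4L,
                        alpha = 0.01, h = NULL) {
  if (!is.infinite(search_radius)) search_radius <- as.integer(search_radius)
  patch_radius <- as.integer(patch_radius)
  road_radius <- as.integer(road_radius)
  road_L <- as.integer(road_L)
  if (patch_radius < 1L || search_radius <= patch_radius)
    stop("need search_radius > patch_radius >= 1", call. = FALSE)
  n_nb <- (2L * road_radius + 1L)^2 - 1L
  if (road_L < 1L || road_L > n_nb)
    stop(sprintf("road_L must lie in [1, %d]", n_nb), call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.null(h) && (!is.numeric(h) || h <= 0)) stop("h must be > 0", call. = FALSE)
  structure(list(search_radius = search_radius, patch_radius = patch_radius,
                 road_radius = road_radius, road_L = road_L,
                 alpha = alpha, h = h),
            class = "pnlm_params")
}

#' @export
print.pnlm_params <- function(x, ...) {
  cat(sprintf(
    "pnlm_params: search r=%s patch f=%d ROAD(radius=%d, L=%d) alpha=%g h=%s\n",
    format(x$search_radius), x$patch_radius, x$road_radius, x$road_L, x$alpha,
    if (is.null(x$h)) "auto (10 * sigma_hat)" else format(x$h)))
  invisible(x)
}

#' Rank-ordered absolute differences (ROAD) statistic
#'
#' At each pixel, the sum of the `road_L` smallest absolute deviations
#' between the pixel and its neighbors in the (2 x road_radius + 1)-square
#' neighborhood (center excluded).  Impulse-like pixels differ from most of
#' their neighbors and score high; pixels in agreement with their
#' surroundings score near zero.
#'
#' @param img Numeric matrix of gray levels.
#' @param params A [pnlm_params()] (only `road_radius` and `road_L` are used).
#' @return Numeric matrix of non-negative ROAD values.
#' @export
road_statistic <- function(img, params = pnlm_params()) {
  assert_gray_image(img)
  cpp_road(img, params$road_radius, params$road_L)
}

#' Probability that a pixel is undamaged
#'
#' Maps the ROAD statistic to a damage-free probability
#' `P = exp(-alpha * ROAD)`: 1 for pixels fully consistent with their
#' neighborhood, decaying towards 0 for impulse-like pixels.
#'
#' @param road Numeric matrix of non-negative ROAD values.
#' @param alpha Positive decay scale (default 0.01).
#' @return Matrix of probabilities in (0, 1\].
#' @export
undamaged_probability <- function(road, alpha = 0.01) {
  if (!is.matrix(road) || !all(is.finite(road)))
    stop("`road` must be a finite numeric matrix", call. = FALSE)
  if (any(road < 0)) stop("`road` contains negative values", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  exp(-alpha * road)
}

#' Probability-weighted squared distance between two patches
#'
#' The squared patch distance of non-local means, with every pixelwise
#' difference damped by the smaller of the two pixels' undamaged
#' probabilities:
#' \deqn{d^2 = \frac{1}{(2f+1)^2} \sum_k \left[\min(p_{i+k}, p_{j+k})\,
#'   (u_{i+k} - u_{j+k})\right]^2.}
#' With all probabilities equal to 1 this is the classical mean-squared patch
#' distance.  Patches extending past the border use mirror padding.
#'
#' @param img Numeric matrix of gray levels.
#' @param P Probability map of the same shape (values in (0, 1\]).
#' @param i,j Length-2 integer vectors `(row, col)` of the two patch centers.
#' @param f Patch radius.
#' @return Non-negative scalar.
#' @export
prob_patch_distance <- function(img, P, i, j, f) {
  assert_gray_image(img)
  assert_same_shape(img, P, "image and probability map")
  f <- as.integer(f)
  U <- cpp_mirror_pad(img, f)
  Q <- cpp_mirror_pad(P, f)
  off <- -f:f
  pi_rows <- i[1] + f + off; pi_cols <- i[2] + f + off
  pj_rows <- j[1] + f + off; pj_cols <- j[2] + f + off
  du <- U[pi_rows, pi_cols, drop = FALSE] - U[pj_rows, pj_cols, drop = FALSE]
  pm <- pmin(Q[pi_rows, pi_cols, drop = FALSE], Q[pj_rows, pj_cols, drop = FALSE])
  sum((pm * du)^2) / (2 * f + 1)^2
}

#' Robust noise standard-deviation estimate
#'
#' Estimates the pixel-noise standard deviation from the median absolute
#' value of the image's Laplacian residuals (kernel
#' `[1 -2 1; -2 4 -2; 1 -2 1]`), scaled for Gaussian consistency: the
#' residual of i.i.d. noise through that kernel has standard deviation
#' 6 sigma, and the median absolute deviation of a Gaussian is 0.6745 sigma.
#' The second difference annihilates constant and linear image structure, so
#' the estimate reflects noise rather than content on the smooth targets this
#' package addresses.
#'
#' @param img Numeric matrix of gray levels.
#' @return Estimated noise standard deviation (gray levels).
#' @export
estimate_noise_sd <- function(img) {
  assert_gray_image(img)
  U <- cpp_mirror_pad(img, 1L)
  H <- nrow(img); W <- ncol(img)
  ctr <- function(dr, dc) U[(1 + dr):(H + dr), (1 + dc):(W + dc), drop = FALSE]
  lap <- 4 * ctr(1, 1) -
    2 * (ctr(0, 1) + ctr(2, 1) + ctr(1, 0) + ctr(1, 2)) +
    (ctr(0, 0) + ctr(0, 2) + ctr(2, 0) + ctr(2, 2))
  median(abs(lap)) / (0.6745 * 6)
}

#' Probability-based non-local means denoising
#'
#' Restores each pixel by a probability-weighted non-local average over its
#' search window:
#' \deqn{\hat u_i = \frac{\sum_j w_{i,j}\, p_j\, u_j}{\sum_j w_{i,j}\, p_j},
#'   \qquad w_{i,j} = \exp(-d^2_{i,j}/h^2),}
#' where \eqn{d^2_{i,j}} is the probability-weighted patch distance
#' ([prob_patch_distance()]) and \eqn{p_j = \exp(-\alpha\,\mathrm{ROAD}(u_j))}
#' the undamaged probability.  Severely damaged pixels therefore lose weight
#' twice: in the patch distance and in the final average.  The center pixel
#' participates with the maximum weight among its competitors (the standard
#' NLM self-weight rule).  With all probabilities forced to 1 the filter is
#' exactly classical NLM.
#'
#' @param img Numeric matrix of gray levels.
#' @param params A [pnlm_params()].
#' @param P Optional probability map overriding the ROAD-derived one
#'   (e.g. a matrix of ones to obtain classical NLM).
#' @return Restored numeric matrix; each pixel lies within the range of its
#'   mirror-padded search window.
#' @export
pnlm_denoise <- function(img, params = pnlm_params(), P = NULL) {
  assert_gray_image(img)
  if (!inherits(params, "pnlm_params")) stop("`params` must be pnlm_params")
  if (is.null(P)) {
    road <- road_statistic(img, params)
    P <- undamaged_probability(road, params$alpha)
  } else {
    assert_same_shape(img, P, "image and probability map")
    if (any(P <= 0) || any(P > 1)) stop("P values must lie in (0, 1]", call. = FALSE)
  }
  if (is.infinite(params$search_radius)) {
    # Whole-image search window: every pairwise weight is 1 in the flat-kernel
    # limit and the restoration is the probability-weighted global mean
    # (the center pixel enters with self-weight 1, i.e. it is included).
    m <- sum(P * img) / sum(P)
    return(matrix(m, nrow(img), ncol(img)))
  }
  h <- params$h
  if (is.null(h)) h <- max(10 * estimate_noise_sd(img), 0.1)
  cpp_pnlm(img, P, params$search_radius, params$patch_radius, h)
}
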