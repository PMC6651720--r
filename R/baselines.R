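#' Lee filter
#'
#' Classical local-statistics despeckle filter:
#' \eqn{\hat u = \mu_w + k (u - \mu_w)} with gain
#' \eqn{k = \sigma_w^2 / (\sigma_w^2 + \sigma_n^2)}, where \eqn{\mu_w} and
#' \eqn{\sigma_w^2} are the window mean and variance and \eqn{\sigma_n^2} a
#' global noise-variance estimate (the median of the local variances, robust
#' to structure, unless supplied).
#'
#' @param img Numeric matrix of gray levels.
#' @param window Odd window side (default 7).
#' @param noise_var Optional fixed noise variance; `NULL` estimates it.
#' @return Filtered numeric matrix.
#' @export
lee_filter <- function(img, window = 7L, noise_var = NULL) {
  assert_gray_image(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  k1 <- rep(1 / window, window)
  mu <- cpp_sep_conv(img, k1)
  v <- pmax(cpp_sep_conv(img * img, k1) - mu^2, 0)
  if (is.null(noise_var)) noise_var <- median(v)
  gain <- if (noise_var == 0) matrix(1, nrow(img), ncol(img)) else v / (v + noise_var)
  mu + gain * (img - mu)
}

#' Adaptive median filter
#'
#' Standard two-stage adaptive median: at each pixel the window grows (from
#' 3 x 3 up to `max_window`) until the window median is not an extremum of
#' the window; the center value is then kept unless it is itself a window
#' extremum (impulse test), in which case the median replaces it.  Mirror
#' padding at the borders.
#'
#' @param img Numeric matrix of gray levels.
#' @param max_window Odd maximum window side (default 9).
#' @return Filtered numeric matrix.
#' @export
adaptive_median <- function(img, max_window = 9L) {
  assert_gray_image(img)
  max_window <- as.integer(max_window)
  if (max_window < 3L || max_window %% 2L == 0L)
    stop("`max_window` must be an odd integer >= 3", call. = FALSE)
  cpp_adaptive_median(img, max_window)
}
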