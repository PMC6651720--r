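#' Average gray level (AGL)
#'
#' Arithmetic mean of all pixels; the biosensing signal of the gray-value
#' detection method.  Conventionally reported to two decimal places.
#'
#' @param img Numeric matrix of gray levels.
#' @return The mean gray level.
#' @export
average_gray <- function(img) {
  assert_gray_image(img)
  mean(img)
}

#' Speckle index (SI)
#'
#' Noise-level metric: standard deviation divided by mean.  `type = "global"`
#' (the default, and the definition used in all reported numbers) computes the
#' ratio over the whole image; `type = "local"` averages the ratio over sliding
#' windows of side `window`, a variant sometimes used in the despeckling
#' literature.  For un-censored multiplicative noise of variance v on a
#' constant image the global SI converges to \eqn{\sqrt v}.
#'
#' @param img Numeric matrix of gray levels with positive mean.
#' @param type `"global"` or `"local"`.
#' @param window Odd window side for `type = "local"` (default 11).
#' @return Non-negative scalar; 0 iff the image is constant (global type).
#' @export
speckle_index <- function(img, type = c("global", "local"), window = 11L) {
  assert_gray_image(img)
  type <- match.arg(type)
  if (type == "global") {
    m <- mean(img)
    if (m <= 0) stop("speckle index undefined: image mean is not positive", call. = FALSE)
    return(sd(img) / m)
  }
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd and >= 3", call. = FALSE)
  k <- rep(1 / window, window)
  mu <- cpp_sep_conv(img, k)
  mu2 <- cpp_sep_conv(img * img, k)
  v <- pmax(mu2 - mu^2, 0)
  if (any(mu <= 0)) stop("speckle index undefined: a window mean is not positive", call. = FALSE)
  mean(sqrt(v) / mu)
}

#' Peak signal-to-noise ratio
#'
#' Standard PSNR with peak 255: \eqn{10\log_{10}(255^2 / \mathrm{MSE})}.
#' Identical images give `Inf`.
#'
#' @param clean,test Numeric matrices of identical shape.
#' @return PSNR in dB.
#' @export
psnr <- function(clean, test) {
  assert_gray_image(clean, "clean")
  assert_gray_image(test, "test")
  assert_same_shape(clean, test)
  mse <- mean((clean - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Equivalent number of looks
#'
#' ENL = mean^2 / variance of a homogeneous region; equals 1/SI^2 wherever
#' both are defined.  Constant images give `Inf`.
#'
#' @param img Numeric matrix of gray levels.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
enl <- function(img) {
  assert_gray_image(img)
  v <- sd(img)^2
  if (v == 0) return(Inf)
  mean(img)^2 / v
}

#' Summarize restoration metrics for an image
#'
#' @param img Image to evaluate.
#' @param clean Optional reference image for PSNR.
#' @return A one-row data frame with columns `agl`, `si`, `psnr`, `enl`
#'   (AGL rounded to 2 decimals and SI to 4 in the print method only; the
#'   stored values are exact).
#' @export
metrics_report <- function(img, clean = NULL) {
  out <- data.frame(agl = average_gray(img),
                    si = speckle_index(img),
                    psnr = if (is.null(clean)) NA_real_ else psnr(clean, img),
                    enl = enl(img))
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  y <- data.frame(agl = sprintf("%.2f", x$agl),
                  si = sprintf("%.4f", x$si),
                  psnr = ifelse(is.na(x$psnr), "-", sprintf("%.2f", x$psnr)),
                  enl = ifelse(is.infinite(x$enl), "Inf", sprintf("%.2f", x$enl)))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
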