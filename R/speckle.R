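#' Describe a multiplicative speckle noise process
#'
#' A speckle specification bundles the parameters of the multiplicative noise
#' model \eqn{I = M (1 + n)} used throughout the package: the corrupted pixel
#' is the clean pixel times one plus a zero-mean random multiplier \eqn{n}
#' of a chosen variance and distribution family.  Clipping to \[0, 255\] and
#' integer quantization emulate an 8-bit camera pipeline; both can be switched
#' off to study the un-censored process.
#'
#' The default (and reference) family is `"uniform"`, i.e.
#' \eqn{n \sim U[-\sqrt{3v}, +\sqrt{3v}]} for variance \eqn{v}, the convention
#' of the classic `speckle` option of image-processing toolboxes.  `"gaussian"`
#' and `"exponential"` (a centred exponential) are provided for robustness
#' checks.
#'
#' @param variance Variance of the zero-mean multiplier \eqn{n}; must be > 0.
#'   Values in (0, 1] correspond to the speckle intensities studied here.
#' @param family One of `"uniform"`, `"gaussian"`, `"exponential"`.
#' @param clip Clip the product to \[0, 255\]?  Default `TRUE`.
#' @param quantize Round the product to integer gray levels?  Default `TRUE`.
#' @param seed Optional integer seed making the realization deterministic;
#'   `NULL` draws from the current RNG stream.
#' @return An object of class `"speckle_spec"`.
#' @examples
#' sp <- speckle_spec(variance = 0.5, seed = 1)
#' img <- constant_image(40)
#' noisy <- add_speckle(img, sp)
#' average_gray(noisy)
#' @export
speckle_spec <- function(variance,
                         family = c("uniform", "gaussian", "exponential"),
                         clip = TRUE, quantize = TRUE, seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0)
    stop("`variance` must be a single positive number", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(variance = variance, family = family,
                 clip = isTRUE(clip), quantize = isTRUE(quantize), seed = seed),
            class = "speckle_spec")
}

#' @export
print.speckle_spec <- function(x, ...) {
  cat(sprintf("speckle_spec: family=%s variance=%g clip=%s quantize=%s seed=%s\n",
              x$family, x$variance, x$clip, x$quantize,
              if (is.null(x$seed)) "<stream>" else x$seed))
  invisible(x)
}

#' Create a constant gray image
#'
#' @param gray Gray level of every pixel.
#' @param size Image dimensions `c(height, width)`; default 256 x 256.
#' @return A numeric matrix.
#' @export
constant_image <- function(gray, size = c(256, 256)) {
  matrix(as.numeric(gray), nrow = size[1], ncol = size[2])
}

# Draw the zero-mean multiplier n with Var[n] = v for a given family.
draw_multiplier <- function(n, variance, family) {
  switch(family,
    uniform = {
      a <- sqrt(3 * variance)
      runif(n, min = -a, max = a)
    },
    gaussian = rnorm(n, mean = 0, sd = sqrt(variance)),
    exponential = {
      s <- sqrt(variance)
      rexp(n, rate = 1 / s) - s
    })
}

#' Corrupt an image with multiplicative speckle noise
#'
#' Applies the model \eqn{I(i,j) = M(i,j)\,(1 + n(i,j))} pixelwise, with
#' \eqn{n} zero-mean of the variance and family given in `spec`, followed by
#' optional clipping to \[0, 255\] and rounding to integer gray levels.
#'
#' @param img Numeric matrix of gray levels (the clean image).
#' @param spec A [speckle_spec()].
#' @return A numeric matrix of the same shape.
#' @export
add_speckle <- function(img, spec) {
  assert_gray_image(img)
  if (!inherits(spec, "speckle_spec")) stop("`spec` must be a speckle_spec")
  with_seed(spec$seed, {
    n <- draw_multiplier(length(img), spec$variance, spec$family)
    out <- img * (1 + n)
    if (spec$clip) out <- pmin(pmax(out, 0), 255)
    if (spec$quantize) out <- round(out)
    matrix(out, nrow = nrow(img), ncol = ncol(img))
  })
}

#' Intensity density of a single speckle pattern
#'
#' The intensity of one fully developed speckle pattern is exponentially
#' distributed: density \eqn{(1/\bar I)\exp(-I/\bar I)} for \eqn{I \ge 0},
#' zero otherwise.
#'
#' @param I Intensity value(s) at which to evaluate the density.
#' @param Ibar Mean intensity of the pattern; must be > 0.
#' @return Density value(s).
#' @export
intensity_pdf_single <- function(I, Ibar) {
  if (!is.numeric(Ibar) || length(Ibar) != 1L || !is.finite(Ibar) || Ibar <= 0)
    stop("`Ibar` must be a single positive number", call. = FALSE)
  ifelse(I >= 0, exp(-I / Ibar) / Ibar, 0)
}

#' Intensity density of the sum of N independent speckle patterns
#'
#' The sum of N independent exponential speckle intensities with common mean
#' `I0` has a gamma density \eqn{I^{N-1}/(\Gamma(N) I_0^N)\, \exp(-I/I_0)} for
#' \eqn{I \ge 0}.  At N = 1 it reduces to [intensity_pdf_single()]; as N grows
#' it approaches a Gaussian (skewness \eqn{2/\sqrt N}).
#'
#' @param I Intensity value(s).
#' @param N Number of superposed patterns (integer >= 1).
#' @param I0 Per-pattern mean intensity; must be > 0.
#' @return Density value(s).
#' @export
intensity_pdf_sum <- function(I, N, I0) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("`N` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(I0) || length(I0) != 1L || !is.finite(I0) || I0 <= 0)
    stop("`I0` must be a single positive number", call. = FALSE)
  ifelse(I >= 0, dgamma(pmax(I, 0), shape = N, scale = I0), 0)
}

#' Fraction of singular (abnormally bright) pixels
#'
#' A pixel is counted as singular when its noisy value is at least twice the
#' corresponding clean value.  Under the uniform multiplier dialect this
#' fraction is exactly zero for variances up to 1/3 (the multiplier support
#' never reaches 2) and grows beyond, reaching
#' \eqn{(\sqrt3 - 1)/(2\sqrt3) \approx 0.2113} at variance 1 before
#' quantization.
#'
#' @param noisy,clean Numeric matrices of identical shape.
#' @return Fraction in \[0, 1\].
#' @export
singular_fraction <- function(noisy, clean) {
  assert_gray_image(noisy, "noisy")
  assert_gray_image(clean, "clean")
  assert_same_shape(noisy, clean)
  mean(noisy >= 2 * clean)
}
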