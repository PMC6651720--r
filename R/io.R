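#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file into a numeric matrix of gray levels on
#' \[0, 255\].  RGB(A) images are converted to luminance with the Rec. 601
#' weights (0.299 R + 0.587 G + 0.114 B); inputs with a bit depth above 8
#' are rescaled to \[0, 255\] with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix of gray levels.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    bits <- attr(x, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(x, "bits.per.sample")
  } else {
    stop(sprintf("unsupported image format '%s': %s", ext, path), call. = FALSE)
  }
  if (!is.null(bits) && length(bits) && !is.na(bits[1]) && bits[1] > 8)
    warning(sprintf("%d-bit input rescaled to [0, 255]", bits[1]))
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    x <- if (nc >= 3L) 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
         else x[, , 1]
  }
  matrix(as.numeric(x) * 255, nrow(x), ncol(x))
}

#' Write an image as 8-bit grayscale
#'
#' Clamps to \[0, 255\], rounds to integer gray levels and writes PNG or
#' TIFF according to the file extension.  Writing then reading an integer
#' valued image on \[0, 255\] is lossless.
#'
#' @param img Numeric matrix of gray levels.
#' @param path Output path (`.png`, `.tif` or `.tiff`).
#' @return The path, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  x <- round(pmin(pmax(img, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(x, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(x, path, bits.per.sample = 8L)
  else stop(sprintf("unsupported image format '%s': %s", ext, path), call. = FALSE)
  invisible(path)
}

#' Generate a batch of noisy constant-gray images
#'
#' Writes `n` speckle-corrupted constant-gray images plus an index CSV
#' (filename, clean_gray, variance, seed) to a directory.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of images.
#' @param gray Clean gray level.
#' @param variance Speckle variance.
#' @param seed Base seed; image k uses `seed + k`.
#' @param size Image dimensions.
#' @param family Noise family.
#' @return Data frame of the index, invisibly.
#' @export
simulate_batch <- function(dir, n = 10L, gray = 40, variance = 0.5, seed = 0L,
                           size = c(256L, 256L), family = "uniform") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clean <- constant_image(gray, size)
  idx <- lapply(seq_len(n), function(k) {
    s <- as.integer(seed) + k
    img <- add_speckle(clean, speckle_spec(variance, family = family, seed = s))
    fn <- sprintf("speckle_g%03d_v%03.0f_%04d.png", gray, 100 * variance, k)
    write_gray_image(img, file.path(dir, fn))
    data.frame(filename = fn, clean_gray = gray, variance = variance, seed = s)
  })
  idx <- do.call(rbind, idx)
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}
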