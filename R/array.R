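#' Geometry of a microarray-unit grid
#'
#' Describes the circular reaction units of a microcavity array image: either
#' an explicit list of disk centers or a regular rows x cols lattice built
#' from a pitch and an origin.  Units must not overlap.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param unit_radius Disk radius in pixels.
#' @param pitch Center-to-center spacing in pixels (used when `unit_centers`
#'   is NULL); must be at least `2 * unit_radius`.
#' @param origin Center of the first (top-left) unit, `c(row, col)`; default
#'   `c(pitch, pitch)`.
#' @param unit_centers Optional n x 2 matrix of (row, col) centers overriding
#'   the regular lattice; must have `rows * cols` rows (row-major unit order).
#' @param background_gray Background gray level used by [synth_array_image()].
#' @return Object of class `"array_grid_spec"`.
#' @export
array_grid_spec <- function(rows, cols, unit_radius, pitch = NULL,
                            origin = NULL, unit_centers = NULL,
                            background_gray = 8) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be positive", call. = FALSE)
  if (!is.numeric(unit_radius) || unit_radius <= 0)
    stop("`unit_radius` must be > 0", call. = FALSE)
  if (is.null(unit_centers)) {
    if (is.null(pitch)) pitch <- ceiling(2.5 * unit_radius)
    if (pitch < 2 * unit_radius)
      stop("units overlap: pitch < 2 * unit_radius", call. = FALSE)
    if (is.null(origin)) origin <- c(pitch, pitch)
    unit_centers <- as.matrix(expand.grid(
      row = origin[1] + (seq_len(rows) - 1L) * pitch,
      col = origin[2] + (seq_len(cols) - 1L) * pitch))
    # expand.grid varies rows fastest; reorder row-major (unit index runs
    # along columns within a row of the array)
    unit_centers <- unit_centers[order(unit_centers[, 1], unit_centers[, 2]), ,
                                 drop = FALSE]
  } else {
    unit_centers <- as.matrix(unit_centers)
    if (nrow(unit_centers) != rows * cols || ncol(unit_centers) != 2L)
      stop("`unit_centers` must be a (rows*cols) x 2 matrix", call. = FALSE)
    dmin <- min(stats::dist(unit_centers))
    if (dmin < 2 * unit_radius)
      stop("units overlap: minimal center distance < 2 * unit_radius", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, unit_radius = unit_radius,
                 unit_centers = unit_centers,
                 background_gray = background_gray),
            class = "array_grid_spec")
}

#' @export
print.array_grid_spec <- function(x, ...) {
  cat(sprintf("array_grid_spec: %d x %d units, radius %g px, background %g\n",
              x$rows, x$cols, x$unit_radius, x$background_gray))
  invisible(x)
}

# Logical disk mask for unit k of a grid in an H x W frame.
unit_mask <- function(grid, k, H, W) {
  ctr <- grid$unit_centers[k, ]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - ctr[1])^2 + (cc - ctr[2])^2 <= grid$unit_radius^2
}

check_grid_in_image <- function(grid, H, W) {
  ctr <- grid$unit_centers; r <- grid$unit_radius
  if (any(ctr[, 1] - r < 1) || any(ctr[, 1] + r > H) ||
      any(ctr[, 2] - r < 1) || any(ctr[, 2] + r > W))
    stop("array unit extends outside the image", call. = FALSE)
  invisible(NULL)
}

#' Synthesize a microarray image
#'
#' Paints the unit disks at `unit_gray` on a `background_gray` background and
#' corrupts the whole frame with multiplicative speckle — a synthetic
#' stand-in for a CCD acquisition of a PSi microcavity array.
#'
#' @param grid An [array_grid_spec()].
#' @param unit_gray Gray level of every unit disk (a scalar, or a
#'   `rows * cols` vector in row-major unit order).
#' @param spec A [speckle_spec()], or NULL for a clean image.
#' @param size Image dimensions `c(height, width)`; default fits the grid
#'   with one pitch of margin.
#' @return Numeric matrix.
#' @export
synth_array_image <- function(grid, unit_gray, spec = NULL, size = NULL) {
  if (!inherits(grid, "array_grid_spec")) stop("`grid` must be an array_grid_spec")
  if (is.null(size)) {
    r <- grid$unit_radius
    size <- c(ceiling(max(grid$unit_centers[, 1]) + 2 * r),
              ceiling(max(grid$unit_centers[, 2]) + 2 * r))
  }
  H <- size[1]; W <- size[2]
  check_grid_in_image(grid, H, W)
  n_units <- grid$rows * grid$cols
  unit_gray <- rep_len(unit_gray, n_units)
  img <- matrix(grid$background_gray, H, W)
  for (k in seq_len(n_units)) img[unit_mask(grid, k, H, W)] <- unit_gray[k]
  if (!is.null(spec)) img <- add_speckle(img, spec)
  img
}

#' Per-unit gray-level quantification
#'
#' Measures the average gray level of every unit disk, plus the overall AGL
#' and speckle index pooled over the union of all unit pixels (the background
#' is excluded everywhere).
#'
#' @param img Numeric matrix of gray levels.
#' @param grid An [array_grid_spec()] valid for the image.
#' @return Object of class `"unit_report"`: list with `per_unit_agl`
#'   (rows x cols matrix), `overall_agl`, `overall_si`, and `n_pixels` per
#'   unit.
#' @export
measure_units <- function(img, grid) {
  assert_gray_image(img)
  if (!inherits(grid, "array_grid_spec")) stop("`grid` must be an array_grid_spec")
  H <- nrow(img); W <- ncol(img)
  check_grid_in_image(grid, H, W)
  n_units <- grid$rows * grid$cols
  agl <- numeric(n_units); npx <- integer(n_units)
  pooled <- logical(length(img))
  for (k in seq_len(n_units)) {
    m <- unit_mask(grid, k, H, W)
    agl[k] <- mean(img[m])
    npx[k] <- sum(m)
    pooled <- pooled | as.vector(m)
  }
  vals <- img[matrix(pooled, H, W)]
  structure(list(per_unit_agl = matrix(agl, grid$rows, grid$cols, byrow = TRUE),
                 overall_agl = mean(vals),
                 overall_si = sd(vals) / mean(vals),
                 n_pixels = npx),
            class = "unit_report")
}

#' @export
print.unit_report <- function(x, ...) {
  cat("Per-unit average gray levels:\n")
  print(round(x$per_unit_agl, 2))
  cat(sprintf("Overall AGL %.2f, SI %.4f over %d unit pixels\n",
              x$overall_agl, x$overall_si, sum(x$n_pixels)))
  invisible(x)
}

#' Restore the gray level of every microarray unit
#'
#' Applies the PNLM-G restoration per segmented unit, mirroring the
#' acquisition workflow in which the array image is segmented into unit
#' images before quantification.  For each unit the largest axis-aligned
#' square inscribed in the disk is cropped (so the crop is a homogeneous
#' scene), restored with [pnlm_g()], and the restored gray level is assigned
#' to the whole disk; background pixels are left at their median-repaired
#' values.
#'
#' @param img Numeric matrix of gray levels (the noisy array image).
#' @param grid An [array_grid_spec()] valid for the image.
#' @param ... Further arguments passed to [pnlm_g()].
#' @return A list with `image` (the restored frame) and `report`
#'   (the [measure_units()] result on the restored frame).
#' @export
restore_units <- function(img, grid, ...) {
  assert_gray_image(img)
  if (!inherits(grid, "array_grid_spec")) stop("`grid` must be an array_grid_spec")
  H <- nrow(img); W <- ncol(img)
  check_grid_in_image(grid, H, W)
  half <- floor(grid$unit_radius / sqrt(2))
  if (half < 1) stop("unit_radius too small to inscribe a crop", call. = FALSE)
  out <- median_repair(img, matrix(TRUE, H, W), 9L)
  for (k in seq_len(grid$rows * grid$cols)) {
    ctr <- round(grid$unit_centers[k, ])
    crop <- img[(ctr[1] - half):(ctr[1] + half),
                (ctr[2] - half):(ctr[2] + half), drop = FALSE]
    fit <- pnlm_g(crop, ...)
    out[unit_mask(grid, k, H, W)] <- average_gray(fit$image)
  }
  list(image = out, report = measure_units(out, grid))
}

#' Ordinary least-squares line fit
#'
#' Fits `y = slope * x + intercept` by OLS and reports the coefficient of
#' determination — the machinery behind the gray-value vs incidence-angle and
#' gray-value vs refractive-index calibration lines.
#'
#' @param x,y Numeric vectors of equal length (>= 3 points; x not all equal).
#' @return Object of class `"linear_fit"`: list with `slope`, `intercept`,
#'   `r2`, and the underlying `lm` fit.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0) stop("degenerate fit: x values are all equal", call. = FALSE)
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = r2, fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: Y = %.4g X + %.4g,  R2 = %.4g\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Convert a gray-level change to a refractive-index change
#'
#' Inverts a calibration line fitted to (refractive-index change, gray-value
#' change) pairs: `delta_n = (delta_gray - intercept) / slope`.
#'
#' @param delta_gray Observed gray-level change(s).
#' @param calib A [fit_line()] result from user-supplied calibration data.
#' @return Refractive-index change(s).
#' @export
gray_to_index <- function(delta_gray, calib) {
  if (!inherits(calib, "linear_fit")) stop("`calib` must be a linear_fit")
  if (calib$slope == 0) stop("calibration slope is zero", call. = FALSE)
  (delta_gray - calib$intercept) / calib$slope
}
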