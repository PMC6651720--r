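# Independent brute-force oracles, written directly from the definitions and
# kept free of the package's C++ code paths.

# Half-sample symmetric reflection of index i into 1..n.
ref_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

ref_pad <- function(img, pad) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H + 2 * pad, W + 2 * pad)
  for (i in seq_len(H + 2 * pad))
    for (j in seq_len(W + 2 * pad))
      out[i, j] <- img[ref_idx(i - pad, H), ref_idx(j - pad, W)]
  out
}

# ROAD: sum of the L smallest absolute deviations from the center over the
# (2*radius+1)^2 neighborhood, center excluded.
ref_road <- function(img, radius = 1L, L = 4L) {
  H <- nrow(img); W <- ncol(img)
  pad <- ref_pad(img, radius)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    nb <- pad[(i):(i + 2 * radius), (j):(j + 2 * radius)]
    d <- abs(as.vector(nb) - img[i, j])
    d <- sort(d[-((length(d) + 1) / 2)])   # drop the center (deviation 0 slot)
    out[i, j] <- sum(sort(d)[seq_len(L)])
  }
  out
}

# Probability-weighted patch distance, literal summation.
ref_patch_dist <- function(U, P, i, j, f) {
  s <- 0
  for (ki in -f:f) for (kj in -f:f) {
    du <- U[i[1] + ki, i[2] + kj] - U[j[1] + ki, j[2] + kj]
    pm <- min(P[i[1] + ki, i[2] + kj], P[j[1] + ki, j[2] + kj])
    s <- s + (pm * du)^2
  }
  s / (2 * f + 1)^2
}

# Full PNLM restoration: double loop over pixels and search offsets.
ref_pnlm <- function(img, P, r, f, h) {
  H <- nrow(img); W <- ncol(img)
  pad <- r + f
  U <- ref_pad(img, pad)
  Q <- ref_pad(P, pad)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ci <- c(i + pad, j + pad)
    num <- 0; den <- 0; wmax <- 0
    for (ti in -r:r) for (tj in -r:r) {
      if (ti == 0 && tj == 0) next
      cj <- ci + c(ti, tj)
      d2 <- ref_patch_dist(U, Q, ci, cj, f)
      w <- exp(-d2 / h^2)
      num <- num + w * Q[cj[1], cj[2]] * U[cj[1], cj[2]]
      den <- den + w * Q[cj[1], cj[2]]
      wmax <- max(wmax, w)
    }
    num <- num + wmax * P[i, j] * img[i, j]
    den <- den + wmax * P[i, j]
    out[i, j] <- num / den
  }
  out
}

# Four-direction gradient of a (smoothed) image, literal substitution.
ref_gradient <- function(S) {
  H <- nrow(S); W <- ncol(S)
  pad <- ref_pad(S, 1L)
  gx <- g45 <- g135 <- gy <- matrix(0, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    a <- function(dx, dy) pad[x + 1 + dx, y + 1 + dy]
    gx[x, y] <- a(1, 0) - a(-1, 0)
    gy[x, y] <- a(0, 1) - a(0, -1)
    g45[x, y] <- a(-1, 1) - a(1, -1)
    g135[x, y] <- a(1, 1) - a(-1, -1)
  }
  list(gx = gx, gy = gy, g45 = g45, g135 = g135,
       magnitude = sqrt(gx^2 + gy^2 + g45^2 + g135^2))
}

# Selective median repair via explicit sorting.
ref_masked_median <- function(img, mask, window) {
  H <- nrow(img); W <- ncol(img)
  f <- window %/% 2
  pad <- ref_pad(img, f)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j]) next
    win <- pad[i:(i + 2 * f), j:(j + 2 * f)]
    out[i, j] <- sort(as.vector(win))[(window^2 + 1) / 2]
  }
  out
}

# Lee filter from the closed-form local statistics.
ref_lee <- function(img, window, noise_var = NULL) {
  H <- nrow(img); W <- ncol(img)
  f <- window %/% 2
  pad <- ref_pad(img, f)
  mu <- v <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    win <- as.vector(pad[i:(i + 2 * f), j:(j + 2 * f)])
    mu[i, j] <- mean(win)
    v[i, j] <- mean(win^2) - mean(win)^2
  }
  v <- pmax(v, 0)
  if (is.null(noise_var)) noise_var <- median(v)
  k <- if (noise_var == 0) matrix(1, H, W) else v / (v + noise_var)
  mu + k * (img - mu)
}

# Two-stage adaptive median, literal translation of the textbook algorithm.
ref_adaptive_median <- function(img, max_window) {
  H <- nrow(img); W <- ncol(img)
  fmax <- max_window %/% 2
  pad <- ref_pad(img, fmax)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    z <- img[i, j]
    res <- z
    w <- 3
    repeat {
      f <- w %/% 2
      win <- as.vector(pad[(i + fmax - f):(i + fmax + f),
                           (j + fmax - f):(j + fmax + f)])
      zmin <- min(win); zmax <- max(win); zmed <- sort(win)[(w^2 + 1) / 2]
      if (zmed > zmin && zmed < zmax) {
        res <- if (z > zmin && z < zmax) z else zmed
        break
      }
      res <- zmed
      w <- w + 2
      if (w > max_window) break
    }
    out[i, j] <- res
  }
  out
}

# OLS via the normal equations.
ref_fit_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

rand_image <- function(n, m = n, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(n * m, lo, hi), n, m)
}
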