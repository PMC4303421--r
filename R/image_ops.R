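# ---------------------------------------------------------------------------
# Core image operators.  All operate on grey image items; intensities are
# promoted to doubles internally and re-quantized half-up.  Each operator is
# also registered with the operator framework (see register_builtin_ops).
# ---------------------------------------------------------------------------

#' Intensity histogram of a grey image
#'
#' @param image A grey `image_item`.
#' @return List with `counts` (one bin per intensity level, 256 for grey8,
#'   65536 for grey16) and `n_pixels`; `sum(counts) == n_pixels`.
#' @export
histogram <- function(image) {
  check_grey(image, "histogram")
  L <- sample_model_max(image$sample_model)
  counts <- tabulate(as.vector(image$pixels) + 1L, nbins = L + 1L)
  list(counts = counts, n_pixels = length(image$pixels))
}

#' Linear histogram normalization (contrast stretch)
#'
#' Maps intensities to `round((v - min) / (max - min) * L)` with `L` the top
#' of the sample model's range (rounding half-up).  Constant images are
#' returned unchanged; for non-constant input the output spans the full
#' range.  Idempotent on images that already span `[0, L]`.
#'
#' @param image A grey `image_item`.
#' @return The stretched `image_item`.
#' @export
normalize_histogram <- function(image) {
  check_grey(image, "normalize_histogram")
  px <- image$pixels
  lo <- min(px); hi <- max(px)
  if (hi == lo) return(image)
  L <- sample_model_max(image$sample_model)
  out <- round_half_up((px - lo) / (hi - lo) * L)
  image_item(matrix(out, nrow = nrow(px)), image$sample_model,
             name = image$name)
}

#' Absolute difference of two grey images
#'
#' @param a,b Grey `image_item`s with identical shape and sample model.
#' @return Per-pixel `|a - b|` in the same sample model.
#' @export
abs_difference <- function(a, b) {
  check_grey(a, "abs_difference"); check_grey(b, "abs_difference")
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop_validation(sprintf(
      "shape mismatch: %dx%d vs %dx%d", nrow(a$pixels), ncol(a$pixels),
      nrow(b$pixels), ncol(b$pixels)))
  if (a$sample_model != b$sample_model)
    stop_validation(sprintf("sample model mismatch: %s vs %s",
                            a$sample_model, b$sample_model))
  image_item(abs(a$pixels - b$pixels), a$sample_model,
             name = paste0("|", a$name, "-", b$name, "|"))
}

#' Histogram statistics: energy, entropy, skewness, kurtosis
#'
#' With `p_i = counts_i / n_pixels` over intensity levels `i`:
#' energy `= sum(p_i^2)`; entropy `= -sum(p_i log2 p_i)` (bits, over
#' occupied bins); and with `mu = sum(i p_i)`, `sigma^2 = sum(p_i (i-mu)^2)`:
#' skewness `= sum(p_i (i-mu)^3) / sigma^3` and (non-excess) kurtosis
#' `= sum(p_i (i-mu)^4) / sigma^4`.  For a single-bin histogram
#' (`sigma = 0`) skewness and kurtosis are 0 by convention so downstream
#' signals stay numeric.  The intensity-level index is used as the variable;
#' any affine rescaling leaves skewness and kurtosis unchanged.
#'
#' @param image A grey `image_item`.
#' @return List with `energy`, `entropy`, `skewness`, `kurtosis`.
#' @export
histogram_statistics <- function(image) {
  h <- histogram(image)
  p <- h$counts / h$n_pixels
  occ <- p > 0
  i <- seq_along(p) - 1
  energy <- sum(p^2)
  entropy <- -sum(p[occ] * log2(p[occ]))
  mu <- sum(i * p)
  s2 <- sum(p * (i - mu)^2)
  if (s2 == 0) {
    skewness <- 0; kurtosis <- 0
  } else {
    skewness <- sum(p * (i - mu)^3) / s2^1.5
    kurtosis <- sum(p * (i - mu)^4) / s2^2
  }
  list(energy = energy, entropy = entropy, skewness = skewness,
       kurtosis = kurtosis)
}

#' Mean grey value
#' @param image A grey `image_item`.
#' @return Arithmetic mean of all pixel intensities.
#' @export
mean_grey <- function(image) {
  check_grey(image, "mean_grey")
  mean(image$pixels)
}

# Reflect-pad a matrix by `e` pixels on every side (mirror about the edge
# pixel, edge not duplicated): row -1 maps to row 1, etc.
reflect_pad <- function(m, e) {
  if (e == 0L) return(m)
  M <- nrow(m); N <- ncol(m)
  if (M < 2L || N < 2L)
    stop_parameter("reflection padding requires at least 2 rows and columns")
  ridx <- c(rev(seq_len(e) + 1L), seq_len(M), M - seq_len(e))
  cidx <- c(rev(seq_len(e) + 1L), seq_len(N), N - seq_len(e))
  if (any(ridx < 1L) || any(cidx < 1L))
    stop_parameter("image too small for the requested padding")
  m[ridx, cidx, drop = FALSE]
}

gaussian_kernel_1d <- function(size, sigma) {
  half <- (size - 1L) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflecting borders; returns doubles.
convolve_separable <- function(px, k) {
  e <- (length(k) - 1L) / 2
  p <- reflect_pad(px, e)
  M <- nrow(px); N <- ncol(px)
  tmp <- matrix(0, M, N + 2L * e)
  for (j in seq_along(k))          # vertical pass
    tmp <- tmp + k[j] * p[(j - 1L) + seq_len(M), , drop = FALSE]
  out <- matrix(0, M, N)
  for (j in seq_along(k))          # horizontal pass
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(N), drop = FALSE]
  out
}

#' Isotropic Gaussian smoothing
#'
#' Convolution with a normalized isotropic Gaussian kernel (weights sum
#' to 1); borders handled by reflection.  Kernel sizes follow the `2i + 1`
#' convention (odd only).
#'
#' @param image A grey `image_item`.
#' @param kernel_size Odd positive kernel width in pixels.
#' @param sigma Positive standard deviation; default `kernel_size / 6` so
#'   the kernel support covers about three sigma on each side.
#' @return The smoothed `image_item` (same sample model).
#' @export
gaussian_smooth <- function(image, kernel_size = 3L, sigma = kernel_size / 6) {
  check_grey(image, "gaussian_smooth")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop_parameter(sprintf(
      "kernel size %d is invalid: sizes follow 2i+1 (odd only)", kernel_size))
  if (sigma <= 0) stop_parameter("sigma must be positive")
  k <- gaussian_kernel_1d(as.integer(kernel_size), sigma)
  out <- convolve_separable(image$pixels, k)
  L <- sample_model_max(image$sample_model)
  image_item(matrix(pmin(pmax(round_half_up(out), 0), L), nrow = nrow(out)),
             image$sample_model, name = image$name)
}

#' Difference-of-Gaussians edge extraction
#'
#' Computes `G(sigma1) * I - G(sigma2) * I` in reals (both convolutions with
#' reflecting borders), then shifts the response by `L/2` and clamps to the
#' sample model for display.  The raw real-valued response is attached as
#' attribute `"response"`.
#'
#' @param image A grey `image_item`.
#' @param sigma1 Narrow Gaussian sigma.
#' @param sigma2 Wide Gaussian sigma; must exceed `sigma1`.
#' @param kernel_size Optional odd kernel width; default covers 3 sigma of
#'   the wider Gaussian.
#' @return Display `image_item` with attribute `"response"` (double matrix).
#' @export
dog_edge <- function(image, sigma1 = 1, sigma2 = 2,
                     kernel_size = 2L * ceiling(3 * sigma2) + 1L) {
  check_grey(image, "dog_edge")
  if (sigma1 <= 0 || sigma2 <= sigma1)
    stop_parameter("requires 0 < sigma1 < sigma2")
  k1 <- gaussian_kernel_1d(kernel_size, sigma1)
  k2 <- gaussian_kernel_1d(kernel_size, sigma2)
  response <- convolve_separable(image$pixels, k1) -
    convolve_separable(image$pixels, k2)
  L <- sample_model_max(image$sample_model)
  shown <- pmin(pmax(round_half_up(response + L / 2), 0), L)
  out <- image_item(matrix(shown, nrow = nrow(response)), image$sample_model,
                    name = paste0("dog(", image$name, ")"))
  attr(out, "response") <- response
  out
}

#' Seeded region growing
#'
#' 4-connected flood fill of all pixels reachable from the seed whose
#' intensity differs from the *seed* intensity by at most `tolerance`
#' (the comparison is against the seed, not a running region mean).
#'
#' @param image A grey `image_item`.
#' @param seed `(row, col)` seed position, 0-based, row 0 at top.
#' @param tolerance Non-negative intensity tolerance.
#' @return List with `mask` (logical matrix, same shape) and `area`
#'   (number of `TRUE` cells).
#' @export
region_grow <- function(image, seed, tolerance = 0) {
  check_grey(image, "region_grow")
  if (tolerance < 0) stop_parameter("tolerance must be non-negative")
  px <- image$pixels
  M <- nrow(px); N <- ncol(px)
  r <- seed[1]; c <- seed[2]
  if (length(seed) != 2L || r < 0 || c < 0 || r >= M || c >= N)
    stop_parameter(sprintf(
      "seed (%s, %s) out of bounds for a %dx%d image", format(seed[1]),
      format(seed[2]), M, N))
  seed_idx <- (c) * M + r + 1L  # column-major linear index, 1-based
  eligible <- abs(px - px[seed_idx]) <= tolerance
  visited <- matrix(FALSE, M, N)
  visited[seed_idx] <- TRUE
  frontier <- seed_idx
  while (length(frontier) > 0L) {
    row0 <- (frontier - 1L) %% M       # 0-based row of each frontier pixel
    up    <- frontier[row0 > 0L] - 1L
    down  <- frontier[row0 < M - 1L] + 1L
    left  <- frontier[frontier > M] - M
    right <- frontier[frontier <= (N - 1L) * M] + M
    nb <- c(up, down, left, right)
    nb <- nb[eligible[nb] & !visited[nb]]
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  list(mask = visited, area = sum(visited))
}

#' Invert a grey image
#'
#' `v' = L - v` with `L` the top of the intensity range; an involution.
#'
#' @param image A grey `image_item`.
#' @return The inverted `image_item`.
#' @export
invert <- function(image) {
  check_grey(image, "invert")
  L <- sample_model_max(image$sample_model)
  image_item(L - image$pixels, image$sample_model, name = image$name)
}
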