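# Fixtures and independent oracles used across the suite.  Everything is
# generated in code; no binary files are shipped.

grey_image <- function(m, model = "grey8", name = "fixture") {
  image_item(m, model, name = name)
}

constant_image <- function(value = 100, M = 8, N = 8, model = "grey8") {
  grey_image(matrix(value, M, N), model)
}

seeded_random_image <- function(seed, M = 16, N = 16, L = 255) {
  set.seed(seed)
  grey_image(matrix(sample.int(L + 1L, M * N, replace = TRUE) - 1L, M, N))
}

# Independent naive LBP reference: per-pixel double loop, scalar bilinear
# interpolation, no shared code with the package implementation.
naive_lbp_codes <- function(pixels, P, R, convention = "paper") {
  M <- nrow(pixels); N <- ncol(pixels)
  e <- ceiling(R)
  # mirror padding about the edge pixel (edge not duplicated)
  ridx <- c(rev(seq_len(e) + 1L), seq_len(M), M - seq_len(e))
  cidx <- c(rev(seq_len(e) + 1L), seq_len(N), N - seq_len(e))
  pad <- pixels[ridx, cidx]
  interp <- function(r, c) {     # 0-based coords in pad
    if (abs(r - round(r)) < 1e-9) r <- round(r)
    if (abs(c - round(c)) < 1e-9) c <- round(c)
    r0 <- floor(r); c0 <- floor(c); fr <- r - r0; fc <- c - c0
    v <- function(rr, cc) pad[rr + 1L, cc + 1L]
    (1 - fr) * (1 - fc) * v(r0, c0) +
      (if (fr > 0) fr * (1 - fc) * v(r0 + 1, c0) else 0) +
      (if (fc > 0) (1 - fr) * fc * v(r0, c0 + 1) else 0) +
      (if (fr > 0 && fc > 0) fr * fc * v(r0 + 1, c0 + 1) else 0)
  }
  codes <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    rc <- i - 1L + e; cc <- j - 1L + e
    center <- pad[rc + 1L, cc + 1L]
    code <- 0
    for (p in 0:(P - 1L)) {
      th <- 2 * pi * p / P
      dr <- -R * sin(th); dc <- R * cos(th)
      if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
      if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
      np <- interp(rc + dr, cc + dc)
      s <- if (convention == "paper") center >= np else np >= center
      if (s) code <- code + 2^p
    }
    codes[i, j] <- code
  }
  codes
}

# Independent rotation-minimization oracle via string rotation.
naive_ri <- function(code, P) {
  bits <- as.integer(intToBits(code))[1:P]
  vals <- vapply(0:(P - 1), function(i) {
    rotated <- bits[((seq_len(P) - 1L + i) %% P) + 1L]  # right shift by i
    sum(rotated * 2^(seq_len(P) - 1L))
  }, 0)
  min(vals)
}

# Small standard synthetic video shared by pipeline tests (kept small so
# the suite stays fast); regenerating with the same arguments is cheap and
# deterministic.
small_timelapse <- function(seed = 11, b = c(15, 45, 70), n = 90,
                            noise = 3, artifacts = integer(0)) {
  generate_timelapse(n, 96, 72, timelapse_truth(b[1], b[2], b[3], artifacts),
                     noise_sigma = noise, seed = seed)
}
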