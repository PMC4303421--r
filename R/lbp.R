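# ---------------------------------------------------------------------------
# Local Binary Patterns with circular bilinear sampling, rotation
# invariance by minimal circular bit rotation, reflecting borders and
# cell-wise descriptor histograms.
#
# Sign convention: the printed definition assigns bit 1 when the *center*
# intensity is greater than or equal to the neighbour (convention "paper").
# This is inverted relative to the common Ojala convention (bit 1 when the
# neighbour >= center), which is available as convention = "standard".  On
# constant images both yield the all-ones code.
# ---------------------------------------------------------------------------

#' Default LBP parameters
#'
#' `P` neighbours (1-32, default 8), radius `R >= 1` (default 1), optional
#' Gaussian pre-smoothing with odd kernel size `k` (default `FALSE`, k = 3),
#' and `C` cells per image side (default 1).
#'
#' @param P Integer number of circular neighbours, `1 <= P <= 32`.
#' @param R Real radius, `R >= 1`.
#' @param smooth Apply Gaussian smoothing before coding?
#' @param k Odd Gaussian kernel size (`k = 2i + 1`, `i <= 50`).
#' @param C Cells per side (`1 <= C <= max(M, N)` of the target image).
#' @return Named parameter list.
#' @export
lbp_params <- function(P = 8L, R = 1.0, smooth = FALSE, k = 3L, C = 1L) {
  list(P = P, R = R, smooth = smooth, k = k, C = C)
}

# Neighbour p sits at angle theta_p = 2*pi*p/P from the +col axis,
# counter-clockwise: (row - R sin theta, col + R cos theta).
lbp_offsets <- function(P, R) {
  p <- seq_len(P) - 1L
  theta <- 2 * pi * p / P
  dr <- -R * sin(theta)
  dc <- R * cos(theta)
  # snap offsets within 1e-9 of an integer grid point
  dr <- ifelse(abs(dr - round(dr)) < 1e-9, round(dr), dr)
  dc <- ifelse(abs(dc - round(dc)) < 1e-9, round(dc), dc)
  list(dr = dr, dc = dc)
}

# Bilinear interpolation of matrix `m` at fractional 0-based (r, c),
# vectorized over equal-length r and c.
bilinear <- function(m, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  M <- nrow(m)
  i00 <- c0 * M + r0 + 1
  v00 <- m[i00]
  v10 <- ifelse(fr > 0, m[i00 + 1], v00)
  v01 <- ifelse(fc > 0, m[i00 + M], v00)
  v11 <- ifelse(fr > 0 & fc > 0, m[i00 + M + 1],
                ifelse(fr > 0, v10, v01))
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Sample the circular neighbourhood of one pixel
#'
#' Neighbour `p` (0-based) sits at angle `2*pi*p/P` measured from the
#' +col axis, counter-clockwise, at distance `R`; in-between positions are
#' bilinearly interpolated from the four surrounding grid points, and
#' positions within 1e-9 of a grid point snap to it exactly.
#'
#' @param image A grey `image_item` (border-extend it first if the circle
#'   leaves the image).
#' @param center `(row, col)`, 0-based.
#' @param P Number of neighbours.
#' @param R Radius.
#' @return Numeric vector of `P` interpolated intensities.
#' @export
sample_neighbours <- function(image, center, P, R) {
  check_grey(image, "sample_neighbours")
  off <- lbp_offsets(P, R)
  r <- center[1] + off$dr
  c <- center[2] + off$dc
  M <- nrow(image$pixels); N <- ncol(image$pixels)
  if (any(r < 0) || any(c < 0) || any(r > M - 1) || any(c > N - 1))
    stop_stackops("stackops_bounds_error", sprintf(
      "sample point outside the image for center (%s, %s), R=%s: extend the borders first",
      format(center[1]), format(center[2]), format(R)))
  bilinear(image$pixels, r, c)
}

#' LBP code of one pixel
#'
#' `code = sum over p of s_p 2^p` with `s_p = 1` when the center intensity
#' is greater than or equal to neighbour `p` (convention `"paper"`), or the
#' reverse comparison under convention `"standard"`.
#'
#' @param center_intensity Real center intensity.
#' @param neighbours Numeric vector of `P` neighbour intensities (P <= 32).
#' @param convention `"paper"` or `"standard"` threshold orientation.
#' @return Integer code in `[0, 2^P - 1]` (returned as a double for P > 30).
#' @export
lbp_code <- function(center_intensity, neighbours,
                     convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  P <- length(neighbours)
  if (P < 1L || P > 32L) stop_parameter("requires 1 <= P <= 32 neighbours")
  s <- if (convention == "paper") center_intensity >= neighbours
       else neighbours >= center_intensity
  sum(as.numeric(s) * 2^(seq_len(P) - 1L))
}

#' Rotation-invariant LBP code
#'
#' Minimum over all circular bit-wise right shifts of the code within a
#' P-bit word; removes the descriptor's orientation dependence.
#' `rotation_invariant(code) <= code`, and the map is idempotent.
#'
#' @param code Code(s) in `[0, 2^P - 1]` (vectorized).
#' @param P Word length in bits (1-32).
#' @return The minimal rotation of each code.
#' @export
rotation_invariant <- function(code, P) {
  if (P < 1L || P > 32L) stop_parameter("requires 1 <= P <= 32")
  top <- 2^P
  if (any(code < 0 | code >= top | code != floor(code)))
    stop_parameter(sprintf("codes must be integers in [0, %s)", format(top)))
  best <- code
  rot <- code
  if (P > 1L) for (i in seq_len(P - 1L)) {
    rot <- floor(rot / 2) + (rot %% 2) * (top / 2)  # right shift by one
    best <- pmin(best, rot)
  }
  best
}

#' Local Binary Pattern transform of an image
#'
#' Optionally smooths the image (Gaussian, kernel `k`, sigma `k/6`), extends
#' the borders by reflection by `ceiling(R)` pixels, computes the LBP code
#' (rotation-invariant if requested) at every original pixel, and partitions
#' the image into `C x C` cells whose code histograms are concatenated into
#' the descriptor.  Code images are scaled to 0-255 for display via
#' `round(code * 255 / (2^P - 1))`.
#'
#' Cell histograms are over raw code values: length `2^P` per cell for
#' `P <= 16`; for larger `P` a dense histogram is not representable and the
#' per-cell histograms cover occupied bins only (named counts).
#'
#' @param image A grey `image_item` (single band).
#' @param params Parameter list from [lbp_params()].
#' @param rotation_invariance Replace each code by its minimal rotation?
#' @param convention Threshold orientation, see [lbp_code()].
#' @return An object of class `lbp_result`: `codes` (raw code matrix),
#'   `code_image` (grey8 display image), `descriptor` (concatenated cell
#'   histogram vector), `cell_histograms` (list of per-cell histograms) and
#'   `code_tables` (one `table_item` of raw codes per cell).
#' @export
lbp_transform <- function(image, params = lbp_params(),
                          rotation_invariance = FALSE,
                          convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  check_grey(image, "the LBP operator")
  params <- utils::modifyList(lbp_params(), params)
  P <- params$P; R <- params$R; C <- params$C
  if (P < 1L || P > 32L)
    stop_validation("Neighbours P outside valid range 1 <= P <= 32")
  if (R < 1.0) stop_validation("Radius R outside valid range R >= 1.0")
  if (params$k %% 2L == 0L || params$k < 3L || params$k > 101L)
    stop_validation("Kernel size k must be odd (k = 2i+1, i <= 50)")
  M <- nrow(image$pixels); N <- ncol(image$pixels)
  if (C < 1L || C > max(M, N))
    stop_validation(sprintf("Cells C outside valid range 1 <= C <= %d",
                            max(M, N)))
  work <- if (isTRUE(params$smooth))
    gaussian_smooth(image, params$k, params$k / 6) else image

  e <- as.integer(ceiling(R))
  padded <- reflect_pad(work$pixels, e)
  off <- lbp_offsets(P, R)
  center <- padded[e + seq_len(M), e + seq_len(N), drop = FALSE]
  rows <- rep(e + seq_len(M) - 1L, times = N)   # 0-based coords in padded
  cols <- rep(e + seq_len(N) - 1L, each = M)
  codes <- matrix(0, M, N)
  for (p in seq_len(P)) {
    v <- bilinear(padded, rows + off$dr[p], cols + off$dc[p])
    s <- if (convention == "paper") as.numeric(center) >= v
         else v >= as.numeric(center)
    codes <- codes + matrix(as.numeric(s), M, N) * 2^(p - 1L)
  }
  if (rotation_invariance)
    codes <- matrix(rotation_invariant(as.vector(codes), P), M, N)

  top <- 2^P - 1
  display <- matrix(round_half_up(codes * 255 / top), M, N)
  code_image <- image_item(display, "grey8",
                           name = paste0("lbp(", image$name, ")"))

  # C x C cell partition; the last row/column of cells absorbs remainders.
  row_brk <- c(floor(M / C) * (seq_len(C) - 1L), M)
  col_brk <- c(floor(N / C) * (seq_len(C) - 1L), N)
  cell_histograms <- list()
  code_tables <- list()
  dense <- P <= 16L
  for (ci in seq_len(C)) for (cj in seq_len(C)) {
    rr <- (row_brk[ci] + 1L):row_brk[ci + 1L]
    cc <- (col_brk[cj] + 1L):col_brk[cj + 1L]
    cell <- codes[rr, cc, drop = FALSE]
    if (dense) {
      h <- tabulate(as.vector(cell) + 1L, nbins = top + 1L)
      names(h) <- NULL
    } else {
      tb <- table(as.vector(cell))
      h <- as.integer(tb)
      names(h) <- names(tb)
    }
    idx <- (ci - 1L) * C + cj
    cell_histograms[[idx]] <- h
    code_tables[[idx]] <- table_item(
      c("row", "col", "code"),
      data.frame(row = rep(rr - 1L, times = length(cc)),
                 col = rep(cc - 1L, each = length(rr)),
                 code = as.vector(cell)),
      name = sprintf("lbp codes cell (%d,%d)", ci, cj))
  }
  descriptor <- unlist(cell_histograms, use.names = FALSE)
  structure(
    list(codes = codes, code_image = code_image, descriptor = descriptor,
         cell_histograms = cell_histograms, code_tables = code_tables,
         P = P, R = R, C = C, rotation_invariance = rotation_invariance),
    class = "lbp_result")
}

#' @export
print.lbp_result <- function(x, ...) {
  cat(sprintf("<lbp_result P=%d R=%s C=%d%s; descriptor length %d>\n", x$P,
              format(x$R), x$C, if (x$rotation_invariance) " (ri)" else "",
              length(x$descriptor)))
  invisible(x)
}
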