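test_that("circular sampling is exact on linear ramps and snaps grid points", {
  ramp <- grey_image(matrix(rep(0:8, each = 9), 9, 9))  # I(r, c) = c
  expect_equal(sample_neighbours(ramp, c(4, 4), 4, 1), c(5, 4, 3, 4))
  nb <- sample_neighbours(ramp, c(4, 4), 8, 1)
  expect_equal(nb[2], 4 + cos(pi / 4))   # p = 1 at 45 degrees
  expect_equal(nb[1], 5)                  # snapped exactly to the grid
  expect_error(sample_neighbours(ramp, c(0, 0), 8, 1),
               class = "stackops_bounds_error")
})

test_that("the code thresholds center against neighbours (ties give 1)", {
  expect_equal(lbp_code(128, rep(128, 8)), 255)
  expect_equal(lbp_code(100, rep(200, 8)), 0)
  expect_equal(lbp_code(50, c(60, 40, 40, 40, 40, 40, 40, 60)), 126)
  # the standard convention inverts the comparison but keeps ties at 1
  expect_equal(lbp_code(50, c(60, 40, 40, 40, 40, 40, 40, 60), "standard"),
               129)
  expect_equal(lbp_code(128, rep(128, 8), "standard"), 255)
  expect_error(lbp_code(1, numeric(0)), class = "stackops_parameter_error")
})

test_that("rotation invariance minimizes over circular shifts", {
  expect_equal(rotation_invariant(255, 8), 255)
  expect_equal(rotation_invariant(2, 8), 1)
  expect_equal(rotation_invariant(129, 8), 3)
  expect_error(rotation_invariant(256, 8), class = "stackops_parameter_error")

  # against the independent string-rotation oracle, all 256 codes
  ours <- rotation_invariant(0:255, 8)
  oracle <- vapply(0:255, naive_ri, 0, P = 8)
  expect_equal(ours, oracle)
  expect_equal(length(unique(ours)), 36L)

  # ri(code) <= code and idempotence, additional word lengths
  for (P in c(4L, 8L, 12L)) {
    codes <- 0:(2^P - 1)
    ri <- rotation_invariant(codes, P)
    expect_true(all(ri <= codes))
    expect_equal(rotation_invariant(ri, P), ri)
  }
})

test_that("the transform matches closed forms on constant images", {
  res <- lbp_transform(constant_image(128), lbp_params(P = 8, R = 1))
  expect_true(all(res$codes == 255))
  expect_true(all(res$code_image$pixels == 255))
  expect_equal(res$descriptor[256], 64)      # all 64 pixels in bin 255
  expect_equal(sum(res$descriptor), 64)

  res10 <- lbp_transform(constant_image(128), lbp_params(P = 10))
  expect_true(all(res10$codes == 1023))
  expect_true(all(res10$code_image$pixels == 255))  # round(1023*255/1023)
})

test_that("cell partitioning concatenates per-cell histograms", {
  img <- seeded_random_image(21, 8, 8)
  res <- lbp_transform(img, lbp_params(P = 8, C = 2))
  expect_length(res$cell_histograms, 4L)
  expect_length(res$descriptor, 4L * 256L)
  for (h in res$cell_histograms) expect_equal(sum(h), 16)  # 4x4 cells
  expect_length(res$code_tables, 4L)
  expect_equal(nrow(res$code_tables[[1]]$data), 16L)
  # remainder rows are absorbed by the last cell row/column
  res2 <- lbp_transform(seeded_random_image(22, 7, 9), lbp_params(C = 2))
  sums <- vapply(res2$cell_histograms, sum, 0)
  expect_equal(sum(sums), 63)
  expect_equal(sums, c(3 * 4, 3 * 5, 4 * 4, 4 * 5))
})

test_that("codes are invariant under monotone grey-scale transforms", {
  # exact for on-grid sampling (P = 4, R = 1); bilinear interpolation does
  # not commute with nonlinear intensity maps, so interpolated patterns
  # are only approximately invariant
  img <- seeded_random_image(31, 12, 12, L = 120)
  monotone <- grey_image(matrix(
    floor(255 * ((img$pixels / 120)^0.5)), 12, 12))
  base <- lbp_transform(img, lbp_params(P = 4, R = 1))$codes
  trans <- lbp_transform(monotone, lbp_params(P = 4, R = 1))$codes
  expect_equal(base, trans)
  # and under affine maps even with interpolation
  affine <- grey_image(img$pixels * 2 + 5)
  expect_equal(lbp_transform(img, lbp_params(P = 8, R = 1))$codes,
               lbp_transform(affine, lbp_params(P = 8, R = 1))$codes)
})

test_that("the transform agrees with the naive double-loop reference", {
  for (case in list(c(8, 1), c(4, 1), c(8, 2))) {
    P <- case[1]; R <- case[2]
    for (seed in 1:3) {
      img <- seeded_random_image(seed + 40, 12, 12)
      fast <- lbp_transform(img, lbp_params(P = P, R = R))$codes
      slow <- naive_lbp_codes(img$pixels, P, R)
      expect_equal(fast, slow, info = sprintf("P=%d R=%g seed=%d", P, R, seed))
    }
  }
})

test_that("ri-code histograms are stable under 90-degree rotation (interior)", {
  img <- seeded_random_image(55, 10, 10)
  rot <- grey_image(t(img$pixels)[10:1, ])  # 90-degree rotation
  a <- lbp_transform(img, lbp_params(P = 8, R = 1), rotation_invariance = TRUE)
  b <- lbp_transform(rot, lbp_params(P = 8, R = 1), rotation_invariance = TRUE)
  interior <- function(codes) tabulate(codes[2:9, 2:9] + 1L, 256L)
  expect_equal(interior(a$codes), interior(b$codes))
})

test_that("optional smoothing and validation guards are applied", {
  img <- seeded_random_image(60, 10, 10)
  smoothed <- lbp_transform(img, lbp_params(smooth = TRUE, k = 3))
  direct <- lbp_transform(gaussian_smooth(img, 3, 0.5), lbp_params())
  expect_equal(smoothed$codes, direct$codes)
  expect_error(lbp_transform(img, lbp_params(P = 33)),
               class = "stackops_validation_error")
  expect_error(lbp_transform(img, lbp_params(R = 0.5)),
               class = "stackops_validation_error")
  expect_error(lbp_transform(img, lbp_params(C = 11)),
               class = "stackops_validation_error")
  expect_error(
    lbp_transform(image_item(array(1, c(4, 4, 3)), "rgb24"), lbp_params()),
    class = "stackops_validation_error")
})
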