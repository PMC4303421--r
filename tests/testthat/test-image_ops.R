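test_that("histogram counts every level and rejects multi-band input", {
  h <- histogram(constant_image(7, 4, 4))
  expect_equal(h$n_pixels, 16L)
  expect_equal(h$counts[8], 16L)
  expect_equal(sum(h$counts), 16L)
  expect_length(h$counts, 256L)

  h2 <- histogram(grey_image(matrix(c(0, 255), 2, 1)))
  expect_equal(h2$counts[c(1, 256)], c(1L, 1L))

  h16 <- histogram(constant_image(30000, 2, 2, "grey16"))
  expect_length(h16$counts, 65536L)
  expect_error(histogram(image_item(array(0, c(2, 2, 3)), "rgb24")),
               class = "stackops_validation_error")
})

test_that("histogram normalization stretches linearly with half-up rounding", {
  img <- grey_image(matrix(c(50, 100, 150, 150), 2, 2))
  out <- normalize_histogram(img)
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[2, 1], 128)  # (50/100)*255 = 127.5, half-up
  expect_equal(out$pixels[1, 2], 255)

  cons <- constant_image(99)
  expect_identical(normalize_histogram(cons), cons)

  # endpoint preservation + exact idempotence on full-range images
  set.seed(3)
  m <- matrix(sample.int(256, 64, TRUE) - 1L, 8, 8)
  m[1] <- 0; m[64] <- 255
  full <- grey_image(m)
  out <- normalize_histogram(full)
  expect_equal(out$pixels, m + 0)
})

test_that("absolute difference is exact, symmetric, and checks shapes", {
  a <- constant_image(200); b <- constant_image(50)
  expect_equal(abs_difference(a, b)$pixels, matrix(150, 8, 8))
  expect_equal(abs_difference(a, a)$pixels, matrix(0, 8, 8))
  x <- seeded_random_image(1); y <- seeded_random_image(2)
  expect_equal(abs_difference(x, y)$pixels, abs_difference(y, x)$pixels)
  err <- tryCatch(abs_difference(constant_image(1, 4, 5),
                                 constant_image(1, 4, 6)),
                  error = function(e) e)
  expect_s3_class(err, "stackops_validation_error")
  expect_match(conditionMessage(err), "4x5")
  expect_match(conditionMessage(err), "4x6")
})

test_that("histogram statistics match closed forms", {
  st <- histogram_statistics(constant_image(77))
  expect_equal(unlist(st), c(energy = 1, entropy = 0, skewness = 0,
                             kurtosis = 0))

  two <- grey_image(matrix(c(0, 255), 4, 4))  # half 0, half 255
  st <- histogram_statistics(two)
  expect_equal(st$energy, 0.5)
  expect_equal(st$entropy, 1)
  expect_equal(st$skewness, 0)
  expect_equal(st$kurtosis, 1)

  uni <- grey_image(matrix(0:255, 16, 16))
  st <- histogram_statistics(uni)
  expect_equal(st$energy, 1 / 256)
  expect_equal(st$entropy, 8)
})

test_that("histogram statistics see only the histogram (permutation invariant)", {
  set.seed(7)
  for (i in 1:5) {
    img <- seeded_random_image(i, 12, 12)
    perm <- grey_image(matrix(sample(as.vector(img$pixels)), 12, 12))
    expect_equal(histogram_statistics(img), histogram_statistics(perm))
  }
})

test_that("mean grey value is the plain pixel average", {
  expect_equal(mean_grey(constant_image(100)), 100)
  expect_equal(mean_grey(grey_image(matrix(c(0, 255), 2, 1))), 127.5)
  split <- grey_image(rbind(matrix(160, 4, 8), matrix(100, 4, 8)))
  expect_equal(mean_grey(split), 130)
})

test_that("gaussian smoothing preserves constants, mass, and the value range", {
  img <- constant_image(200, 10, 10)
  expect_equal(gaussian_smooth(img, 5, 1)$pixels, img$pixels)
  expect_error(gaussian_smooth(img, 4, 1), class = "stackops_parameter_error")

  # impulse response is symmetric and matches direct kernel evaluation
  m <- matrix(0, 9, 9); m[5, 5] <- 255
  sm <- gaussian_smooth(grey_image(m), 5, 1)$pixels
  expect_equal(sm, sm[9:1, ])           # vertical symmetry
  expect_equal(sm, t(sm))               # isotropy
  k <- stackops:::gaussian_kernel_1d(5, 1)
  direct <- floor(255 * outer(k, k)[1:5, 1:5] + 0.5)
  expect_equal(sm[3:7, 3:7], direct)
  expect_lte(abs(sum(sm) - 255), 13)  # mass preserved up to 25 roundings

  set.seed(5)
  for (i in 1:4) {
    img <- seeded_random_image(i, 12, 12)
    out <- gaussian_smooth(img, 7, 1.5)$pixels
    expect_gte(min(out), min(img$pixels))
    expect_lte(max(out), max(img$pixels))
  }
})

test_that("difference-of-Gaussians responds at edges and not in flat areas", {
  img <- constant_image(120, 10, 10)
  out <- dog_edge(img, 1, 2)
  expect_equal(attr(out, "response"), matrix(0, 10, 10))
  expect_equal(out$pixels, matrix(128, 10, 10))  # shifted by L/2

  step <- grey_image(cbind(matrix(40, 12, 16), matrix(220, 12, 16)))
  resp <- attr(dog_edge(step, 1, 2), "response")
  # band-pass response: zero-crossing at the edge, peaks flanking it
  expect_true(unname(which.max(abs(resp[6, ]))) %in% 15:18)
  expect_equal(resp[6, 15], -resp[6, 18])  # antisymmetric about the step
  expect_error(dog_edge(img, 2, 2), class = "stackops_parameter_error")
})

test_that("region growing floods 4-connected pixels within seed tolerance", {
  img <- constant_image(10, 6, 7)
  rg <- region_grow(img, c(0, 0), 0)
  expect_equal(rg$area, 42L)
  expect_true(all(rg$mask))

  # rasterized disc: area equals the independent rasterization count
  M <- 31; N <- 31
  d2 <- outer((1:M - 16)^2, (1:N - 16)^2, "+")
  disc <- matrix(50, M, N); disc[d2 <= 100] <- 200
  rg <- region_grow(grey_image(disc), c(15, 15), 10)
  expect_equal(rg$area, sum(d2 <= 100))
  expect_equal(rg$mask, d2 <= 100)

  expect_error(region_grow(img, c(-1, 0), 0),
               class = "stackops_parameter_error")
  expect_error(region_grow(img, c(0, 7), 0),
               class = "stackops_parameter_error")

  # area is monotone non-decreasing in tolerance
  img <- seeded_random_image(8, 15, 15)
  areas <- vapply(c(0, 10, 30, 80, 300), function(tol)
    region_grow(img, c(7, 7), tol)$area, 0)
  expect_true(all(diff(areas) >= 0))
  expect_equal(areas[5], 225)
})

test_that("inversion is an involution that maps 0 to the range top", {
  expect_equal(invert(constant_image(0))$pixels[1, 1], 255)
  expect_equal(invert(constant_image(65535, 2, 2, "grey16"))$pixels[1, 1], 0)
  img <- seeded_random_image(4)
  expect_equal(invert(invert(img))$pixels, img$pixels + 0)
})
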