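test_that("gaussian kernel is normalized, symmetric, and matches direct evaluation", {
  for (par in list(c(1, 3), c(0.5, 2), c(2, 6), c(3, 9))) {
    k <- build_gaussian_kernel(par[1], par[2])
    expect_length(k$weights, 2 * par[2] + 1)
    expect_equal(sum(k$weights), 1, tolerance = 1e-12)
    expect_equal(k$weights, rev(k$weights))
    expect_true(all(diff(k$weights[(par[2] + 1):(2 * par[2] + 1)]) < 0))
    # independent direct evaluation of the density at each offset
    x <- -par[2]:par[2]
    direct <- exp(-x^2 / (2 * par[1]^2)) / sqrt(2 * pi * par[1]^2)
    expect_equal(k$weights, direct / sum(direct), tolerance = 1e-12)
  }
  # analytic center/neighbor ratio before normalization survives it
  k <- build_gaussian_kernel(1, 1)
  expect_equal(k$weights[2] / k$weights[1], exp(0.5), tolerance = 1e-12)
})

test_that("gaussian kernel rejects bad parameters", {
  expect_error(build_gaussian_kernel(0, 3), "sigma")
  expect_error(build_gaussian_kernel(-1, 3), "sigma")
  expect_error(build_gaussian_kernel(1, 0), "radius")
  expect_error(build_gaussian_kernel(1, 1.5), "radius")
})

test_that("blurring a constant image is an exact identity", {
  img <- array(128, dim = c(10, 12, 3))
  expect_identical(gaussian_blur(img, sigma = 1), img)
  expect_identical(gaussian_blur(img, sigma = 3), img)
  gray <- matrix(77, 9, 9)
  expect_identical(gaussian_blur(gray, sigma = 2), gray)
})

test_that("separable blur equals direct 2-D convolution within one level", {
  # single impulse
  m <- matrix(0, 15, 15); m[8, 8] <- 255
  k <- build_gaussian_kernel(1, 3)
  k2d <- outer(k$weights, k$weights)
  expect_lte(max(abs(gaussian_blur(m, 1, 3) - oracle_conv2d(m, k2d))), 1)
  # random images at several sizes
  set.seed(101)
  k <- build_gaussian_kernel(2, 6)
  k2d <- outer(k$weights, k$weights)
  for (i in 1:10) {
    H <- sample(8:64, 1); W <- sample(8:64, 1)
    m <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
    expect_lte(max(abs(gaussian_blur(m, 2, 6) - oracle_conv2d(m, k2d))), 1)
  }
})

test_that("blur has finite support bounded by the kernel radius", {
  m <- matrix(0, 31, 31); m[16, 16] <- 255
  out <- gaussian_blur(m, sigma = 2, radius = 6)
  expect_equal(out[1, 1], 0)
  expect_equal(out[16, 31], 0)  # 15 > radius away from the impulse
})

test_that("blur rejects empty or malformed input", {
  expect_error(gaussian_blur(array(0, c(0, 4, 3)), 1), "empty|H x W")
  expect_error(gaussian_blur(matrix(300, 2, 2), 1), "\\[0, 255\\]")
})

test_that("hue hits the pure primaries exactly and handles the undefined branch", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(rgb_to_hsv(px(255, 0, 0))[1, 1, 1], 0)
  expect_equal(rgb_to_hsv(px(0, 255, 0))[1, 1, 1], 120)
  expect_equal(rgb_to_hsv(px(0, 0, 255))[1, 1, 1], 240)
  # violet: max = R branch with B > G wraps negative hue
  expect_equal(rgb_to_hsv(px(128, 0, 128))[1, 1, 1], 300)
  # achromatic: hue and saturation forced to zero
  gray <- rgb_to_hsv(px(77, 77, 77))
  expect_equal(gray[1, 1, 1], 0)
  expect_equal(gray[1, 1, 2], 0)
  expect_equal(gray[1, 1, 3], 77 / 255)
  black <- rgb_to_hsv(px(0, 0, 0))
  expect_equal(black[1, 1, 2], 0)
})

test_that("hue agrees with the grDevices reference within 0.5 degrees", {
  set.seed(7)
  img <- random_rgb(24, 24)
  hsv <- rgb_to_hsv(img)
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2])
  b <- as.vector(img[, , 3])
  ref <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  chromatic <- !(r == g & g == b)
  dh <- abs(as.vector(hsv[, , 1])[chromatic] - 360 * ref["h", chromatic])
  dh <- pmin(dh, 360 - dh)
  expect_lt(max(dh), 0.5)
  expect_equal(as.vector(hsv[, , 2])[chromatic],
               unname(ref["s", chromatic]), tolerance = 1e-12)
  expect_equal(as.vector(hsv[, , 3]), unname(ref["v", ]),
               tolerance = 1e-12)
})

test_that("hsv byte export scales hue onto 0-179 by default", {
  px <- array(c(0, 0, 255), c(1, 1, 3))
  bytes <- hsv_to_bytes(rgb_to_hsv(px))
  expect_equal(bytes[1, 1, 1], 120)  # 240 degrees * 0.5
  expect_equal(bytes[1, 1, 3], 255)
})

test_that("binary threshold uses a strict inequality at the midtone point", {
  m <- matrix(c(126, 127, 128), 1)
  expect_equal(as.vector(binary_threshold(m)), c(0, 0, 255))
  expect_equal(binary_threshold(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(binary_threshold(matrix(1, 2, 2), lo = 200, hi = 100),
               "lo < hi")
  # per-pixel loop oracle on a random image
  set.seed(11)
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  out <- binary_threshold(m)
  for (i in 1:8) for (j in 1:8)
    expect_equal(out[i, j], if (m[i, j] > 127) 255 else 0)
})

test_that("bitwise AND keeps pixels only under the white mask", {
  set.seed(12)
  img <- random_rgb(6, 8)
  all_on <- matrix(255, 6, 8)
  expect_identical(bitwise_and(img, all_on), img)
  expect_true(all(bitwise_and(img, matrix(0, 6, 8)) == 0))
  checker <- 255 * outer(1:6, 1:8, function(i, j) (i + j) %% 2)
  out <- bitwise_and(img, checker)
  for (ch in 1:3)
    expect_equal(out[, , ch], img[, , ch] * (checker == 255))
  expect_error(bitwise_and(img, matrix(255, 3, 3)), "dimensions")
})
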