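# ---- internal validators -------------------------------------------------

#' @keywords internal
#' @noRd
assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop(sprintf("`%s` must have channel values in [0, 255]", arg),
         call. = FALSE)
  invisible(image)
}

#' @keywords internal
#' @noRd
assert_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image))
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop(sprintf("`%s` must have values in [0, 255]", arg), call. = FALSE)
  invisible(image)
}

#' @keywords internal
#' @noRd
assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  if (!all(mask %in% c(0, 255)))
    stop(sprintf("`%s` must contain only the values 0 and 255", arg),
         call. = FALSE)
  invisible(mask)
}

# Round half away from zero, then clip to the 8-bit range. All channel
# intensities are non-negative so floor(x + 0.5) is half-away-from-zero.
#' @keywords internal
#' @noRd
clip8 <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}

# ---- Gaussian kernel and separable blur ----------------------------------

#' Build a normalized 1-D Gaussian convolution kernel
#'
#' Evaluates the 1-D Gaussian density `exp(-x^2 / (2 * sigma^2)) /
#' sqrt(2 * pi * sigma^2)` at the integer offsets `-radius, ..., radius`
#' and normalizes the weights to sum exactly to one. The kernel is the
#' building block of the separable two-pass blur used to suppress stain
#' noise and specular reflections before color segmentation.
#'
#' @param sigma Standard deviation of the Gaussian, in pixels. Must be
#'   positive.
#' @param radius Integer half-width of the kernel, in pixels. The kernel has
#'   `2 * radius + 1` taps. Must be at least 1.
#' @return An object of class `gaussian_kernel`: a list with elements
#'   `sigma`, `radius` and `weights` (numeric vector of length
#'   `2 * radius + 1`, symmetric, strictly decreasing from the center,
#'   summing to 1).
#' @examples
#' k <- build_gaussian_kernel(sigma = 1, radius = 3)
#' sum(k$weights)  # 1
#' @export
build_gaussian_kernel <- function(sigma, radius) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1 ||
      radius != as.integer(radius))
    stop("`radius` must be a positive integer", call. = FALSE)
  x <- seq.int(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
  w <- w / sum(w)
  structure(list(sigma = sigma, radius = as.integer(radius), weights = w),
            class = "gaussian_kernel")
}

# 1-D convolution of every row of `m` with kernel weights `w`,
# replicate-border padding. Vectorized as a sum of shifted column blocks.
#' @keywords internal
#' @noRd
conv_rows <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  W <- ncol(m)
  padded <- m[, c(rep.int(1L, r), seq_len(W), rep.int(W, r)), drop = FALSE]
  out <- matrix(0, nrow(m), W)
  for (k in seq_along(w)) {
    out <- out + w[k] * padded[, k:(k + W - 1L), drop = FALSE]
  }
  out
}

#' Separable Gaussian blur
#'
#' Blurs an RGB or grayscale image with a two-pass (horizontal then
#' vertical) convolution against the 1-D kernel from
#' [build_gaussian_kernel()]. The two-pass scheme is algebraically equal to
#' a direct 2-D convolution with the outer-product kernel but needs far
#' fewer multiplications. Borders are handled by edge replication, which
#' avoids the dark halos that zero padding would leak into downstream hue
#' masks. Channel outputs are rounded half-away-from-zero and clipped to
#' [0, 255] once, after both passes.
#'
#' @param image An H x W x 3 RGB array or an H x W grayscale matrix with
#'   values in [0, 255].
#' @param sigma Gaussian standard deviation in pixels (default 2).
#' @param radius Kernel half-width in pixels; defaults to `ceiling(3 *
#'   sigma)`, which captures more than 99 percent of the kernel mass.
#' @return A blurred image of the same type and dimensions as the input.
#' @examples
#' img <- array(128, dim = c(8, 8, 3))
#' identical(gaussian_blur(img, sigma = 1), img)  # constants are preserved
#' @export
gaussian_blur <- function(image, sigma = 2, radius = ceiling(3 * sigma)) {
  kern <- build_gaussian_kernel(sigma, radius)
  w <- kern$weights
  blur_plane <- function(m) conv_rows(t(conv_rows(t(m), w)), w)
  if (is.matrix(image)) {
    assert_gray_image(image)
    return(clip8(blur_plane(image)))
  }
  assert_rgb_image(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- clip8(blur_plane(image[, , ch]))
  out
}

# ---- RGB -> HSV ----------------------------------------------------------

#' Convert an RGB image to HSV
#'
#' Per-pixel hue is computed from the largest of the R, G, B values: with
#' `max` and `min` the channel extremes, `H = (G-B)/(max-min)` when the
#' maximum is R, `2 + (B-R)/(max-min)` when it is G, and `4 + (R-G)/(max-min)`
#' when it is B; negative values are wrapped by adding 6 and the result is
#' scaled by 60 to degrees, so pure red maps to 0, green to 120 and blue to
#' 240 degrees. Achromatic pixels (`max == min`) have no defined hue and are
#' stored with hue 0 and saturation 0, which guarantees their exclusion by
#' any hue mask with a positive saturation floor. Saturation is
#' `(max-min)/max` (0 when `max` is 0) and value is `max/255`.
#'
#' @param image An H x W x 3 RGB array with values in [0, 255].
#' @return An H x W x 3 array of class `hsv_image`: plane 1 holds hue in
#'   degrees in [0, 360), plane 2 saturation in [0, 1], plane 3 value in
#'   [0, 1].
#' @seealso [hsv_to_bytes()] for the scaled 8-bit export of the hue plane.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_hsv(px)[1, 1, 1]  # 0 degrees: red
#' @export
rgb_to_hsv <- function(image) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  r <- matrix(image[, , 1], H, W)
  g <- matrix(image[, , 2], H, W)
  b <- matrix(image[, , 3], H, W)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  chrom <- d > 0
  iR <- chrom & (mx == r)
  iG <- chrom & !iR & (mx == g)
  iB <- chrom & !iR & !iG
  h[iR] <- (g[iR] - b[iR]) / d[iR]
  h[iG] <- 2 + (b[iG] - r[iG]) / d[iG]
  h[iB] <- 4 + (r[iB] - g[iB]) / d[iB]
  h[h < 0] <- h[h < 0] + 6
  h <- h * 60
  h[h >= 360] <- 0
  s <- matrix(0, nrow(r), ncol(r))
  pos <- mx > 0
  s[pos] <- d[pos] / mx[pos]
  v <- mx / 255
  out <- array(c(h, s, v), dim = dim(image))
  class(out) <- c("hsv_image", class(out))
  out
}

#' Export an HSV image to 8-bit planes
#'
#' Packs hue, saturation and value into bytes: hue is multiplied by a scale
#' factor (default 0.5, mapping [0, 360) onto the common 0-179 byte range)
#' and saturation and value are stretched to [0, 255].
#'
#' @param hsv An `hsv_image` array from [rgb_to_hsv()].
#' @param hue_scale Multiplier applied to the hue in degrees before rounding
#'   (default 0.5).
#' @return An H x W x 3 integer-valued array of bytes.
#' @export
hsv_to_bytes <- function(hsv, hue_scale = 0.5) {
  stopifnot(is.array(hsv), length(dim(hsv)) == 3L)
  out <- array(0, dim = dim(hsv))
  out[, , 1] <- clip8(hsv[, , 1] * hue_scale)
  out[, , 2] <- clip8(hsv[, , 2] * 255)
  out[, , 3] <- clip8(hsv[, , 3] * 255)
  out
}

# ---- threshold and bitwise AND -------------------------------------------

#' Fixed binary threshold
#'
#' Maps a grayscale image to a binary mask: pixels strictly greater than
#' `lo` become `hi` (white), all others 0. The 127/255 defaults implement
#' the midtone/white convention used to binarize the cleaned hue mask.
#'
#' @param image H x W grayscale matrix with values in [0, 255].
#' @param lo Threshold; a pixel must exceed it (strictly) to turn white.
#'   Default 127.
#' @param hi Output value for white pixels, default 255.
#' @return A binary mask matrix over {0, `hi`}.
#' @examples
#' binary_threshold(matrix(c(126, 127, 128), 1))  # 0 0 255
#' @export
binary_threshold <- function(image, lo = 127, hi = 255) {
  assert_gray_image(image)
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi > 255 || lo >= hi)
    stop("thresholds must satisfy 0 <= lo < hi <= 255", call. = FALSE)
  out <- matrix(0, nrow(image), ncol(image))
  out[image > lo] <- hi
  out
}

#' Bitwise AND of an image with a binary mask
#'
#' Keeps the original pixel wherever the mask is white (255) and blacks out
#' everything else, producing the "segmented" image in which only pixels
#' inside detected regions retain their color.
#'
#' @param image H x W x 3 RGB array.
#' @param mask H x W binary mask over {0, 255}.
#' @return An RGB array of the same dimensions.
#' @export
bitwise_and <- function(image, mask) {
  assert_rgb_image(image)
  assert_binary_mask(mask)
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("`image` and `mask` dimensions differ", call. = FALSE)
  keep <- mask == 255
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!keep] <- 0
    out[, , ch] <- plane
  }
  out
}

# ---- grayscale helper ----------------------------------------------------

#' Collapse an RGB image to grayscale
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114); intermediate step
#' before fixed thresholding when a color image must be binarized.
#'
#' @param image H x W x 3 RGB array.
#' @return H x W grayscale matrix in [0, 255].
#' @export
rgb_to_gray <- function(image) {
  assert_rgb_image(image)
  clip8(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}
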