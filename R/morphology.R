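# Binary mathematical morphology on {0,255} masks. Pixels outside the image
# are background, so a structuring element never "fits" over the border.

#' Create a binary structuring element
#'
#' @param size Odd side length of the square element (default 5, the kernel
#'   used for speck removal in the segmentation pipeline).
#' @param shape Optional K x K 0/1 matrix overriding the all-ones square; K
#'   must be odd and the center cell must be active.
#' @return An object of class `structuring_element` wrapping the 0/1 grid.
#' @export
structuring_element <- function(size = 5, shape = NULL) {
  if (is.null(shape)) {
    if (size < 1 || size %% 2 == 0)
      stop("`size` must be a positive odd integer", call. = FALSE)
    shape <- matrix(1L, size, size)
  } else {
    if (!is.matrix(shape) || nrow(shape) != ncol(shape) ||
        nrow(shape) %% 2 == 0)
      stop("`shape` must be a square matrix with odd side", call. = FALSE)
    if (!all(shape %in% c(0, 1)) || sum(shape) < 1)
      stop("`shape` must be 0/1 with at least one active cell", call. = FALSE)
    ctr <- (nrow(shape) + 1L) / 2L
    if (shape[ctr, ctr] != 1)
      stop("the origin (center cell) of `shape` must be active", call. = FALSE)
  }
  structure(list(shape = shape, size = nrow(shape)),
            class = "structuring_element")
}

#' @keywords internal
#' @noRd
se_offsets <- function(se, reflect = FALSE) {
  if (inherits(se, "structuring_element")) se <- se$shape
  ctr <- (nrow(se) + 1L) / 2L
  idx <- which(se == 1, arr.ind = TRUE)
  off <- cbind(idx[, 1] - ctr, idx[, 2] - ctr)
  if (reflect) off <- -off
  off
}

# Sum of 0/1 mask shifted by each offset, zero padding outside the frame.
#' @keywords internal
#' @noRd
shift_count <- function(bin, offsets) {
  H <- nrow(bin); W <- ncol(bin)
  r <- max(abs(offsets))
  padded <- matrix(0, H + 2L * r, W + 2L * r)
  padded[(r + 1L):(r + H), (r + 1L):(r + W)] <- bin
  acc <- matrix(0, H, W)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    acc <- acc + padded[(r + 1L + dr):(r + H + dr),
                        (r + 1L + dc):(r + W + dc)]
  }
  acc
}

#' Binary erosion
#'
#' A pixel stays white only where the whole structuring element, centered
#' there, fits inside the white foreground; out-of-image pixels count as
#' background, so foreground touching the border is eroded away. Erosion
#' deletes white specks smaller than the element and shrinks every region.
#'
#' @param mask H x W binary mask over {0, 255}.
#' @param se A [structuring_element()] (default 5 x 5 all-ones).
#' @return Eroded binary mask.
#' @export
erode <- function(mask, se = structuring_element()) {
  assert_binary_mask(mask)
  off <- se_offsets(se)
  cnt <- shift_count((mask == 255) + 0, off)
  (cnt == nrow(off)) * 255
}

#' Binary dilation
#'
#' A pixel turns white where any active cell of the reflected structuring
#' element, centered there, touches a white input pixel. Dilation grows
#' regions back after erosion and smooths ragged edges.
#'
#' @inheritParams erode
#' @return Dilated binary mask.
#' @export
dilate <- function(mask, se = structuring_element()) {
  assert_binary_mask(mask)
  off <- se_offsets(se, reflect = TRUE)
  cnt <- shift_count((mask == 255) + 0, off)
  (cnt >= 1) * 255
}

#' Morphological opening for speck removal
#'
#' Erosion followed by dilation with the same structuring element. Small
#' white noise (anything the element cannot fit into) is removed while
#' larger regions survive with their area roughly preserved. Opening is
#' idempotent and never adds foreground pixels.
#'
#' @inheritParams erode
#' @return Cleaned binary mask.
#' @export
remove_noise <- function(mask, se = structuring_element()) {
  dilate(erode(mask, se), se)
}
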