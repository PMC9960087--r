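# Hue-band segmentation pipeline: blur -> HSV -> hue mask -> opening ->
# threshold -> bitwise AND -> contours.

#' Hue range for color masking
#'
#' Defines the HSV acceptance region for foreground pixels. The default
#' band, 250-340 degrees with a 0.25 saturation and 0.15 value floor,
#' targets the violet/purple of Romanowsky-stained blast nuclei while
#' excluding pale background (low saturation), red/pink erythrocytes
#' (hue near 0/360) and orange eosinophil granules (hue 20-40). When
#' `lower > upper` the band wraps across 360 degrees.
#'
#' @param lower,upper Hue bounds in degrees, each in [0, 360).
#' @param sat_min,val_min Minimum saturation and value in [0, 1].
#' @return An object of class `hue_range`.
#' @export
hue_range <- function(lower = 250, upper = 340, sat_min = 0.25,
                      val_min = 0.15) {
  if (lower < 0 || lower >= 360 || upper < 0 || upper >= 360)
    stop("hue bounds must lie in [0, 360)", call. = FALSE)
  if (sat_min < 0 || sat_min > 1 || val_min < 0 || val_min > 1)
    stop("`sat_min` and `val_min` must lie in [0, 1]", call. = FALSE)
  structure(list(lower = lower, upper = upper, sat_min = sat_min,
                 val_min = val_min), class = "hue_range")
}

#' Mask pixels inside a hue range
#'
#' A pixel is kept (255) when its hue lies inside the range (wrapping
#' across 360 degrees when `lower > upper`) and its saturation and value
#' reach the configured floors; achromatic pixels carry saturation 0 and
#' are therefore always excluded when `sat_min > 0`.
#'
#' @param hsv An `hsv_image` array from [rgb_to_hsv()].
#' @param range A [hue_range()].
#' @return Binary mask over {0, 255}.
#' @export
hue_mask <- function(hsv, range = hue_range()) {
  stopifnot(is.array(hsv), length(dim(hsv)) == 3L)
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  in_h <- if (range$lower <= range$upper) {
    h >= range$lower & h <= range$upper
  } else {
    h >= range$lower | h <= range$upper
  }
  (in_h & s >= range$sat_min & v >= range$val_min) * 255
}

#' Fill unfilled (hole) pixels
#'
#' Stain and sensor dropouts occasionally leave pure-black holes inside
#' otherwise colored regions, which later stages would mistake for
#' features. A hole is a (0,0,0) pixel whose 8-neighborhood is mostly
#' non-black (at least 5 of the available neighbors); each hole is
#' replaced by the per-channel median of its non-black neighbors, computed
#' on the input image so the result does not depend on fill order. Images
#' without holes are returned unchanged.
#'
#' @param image H x W x 3 RGB array.
#' @return RGB array with holes filled.
#' @export
fill_unfilled_pixels <- function(image) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  black <- image[, , 1] == 0 & image[, , 2] == 0 & image[, , 3] == 0
  if (!any(black)) return(image)
  holes <- which(black, arr.ind = TRUE)
  out <- image
  for (k in seq_len(nrow(holes))) {
    r <- holes[k, 1]; c <- holes[k, 2]
    rr <- max(1, r - 1):min(H, r + 1)
    cc <- max(1, c - 1):min(W, c + 1)
    nbr <- as.matrix(expand.grid(rr, cc))
    nbr <- nbr[!(nbr[, 1] == r & nbr[, 2] == c), , drop = FALSE]
    valid <- !black[nbr]
    if (sum(valid) < 5) next
    nbr <- nbr[valid, , drop = FALSE]
    for (ch in 1:3)
      out[r, c, ch] <- clip8(stats::median(image[cbind(nbr, ch)]))
  }
  out
}

#' Bilinear downscale to a maximum dimension
#'
#' Downscales so that `max(H, W) <= max_dim`, preserving aspect ratio, with
#' bilinear interpolation; images already small enough (and any request to
#' upscale) are returned unchanged.
#'
#' @param image H x W x 3 RGB array.
#' @param max_dim Maximum allowed height or width in pixels.
#' @return RGB array, possibly smaller.
#' @export
resize_image <- function(image, max_dim = 1024) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (max(H, W) <= max_dim) return(image)
  scale <- max_dim / max(H, W)
  nH <- max(1L, as.integer(round(H * scale)))
  nW <- max(1L, as.integer(round(W * scale)))
  # source coordinates of target pixel centers
  src_r <- pmin(pmax((seq_len(nH) - 0.5) * H / nH + 0.5, 1), H)
  src_c <- pmin(pmax((seq_len(nW) - 0.5) * W / nW + 0.5, 1), W)
  r0 <- pmin(floor(src_r), H - 1L); r1 <- r0 + 1L; fr <- src_r - r0
  c0 <- pmin(floor(src_c), W - 1L); c1 <- c0 + 1L; fc <- src_c - c0
  out <- array(0, dim = c(nH, nW, 3))
  for (ch in 1:3) {
    m <- image[, , ch]
    rows <- m[r0, , drop = FALSE] * (1 - fr) + m[r1, , drop = FALSE] * fr
    mixed <- sweep(rows[, c0, drop = FALSE], 2, 1 - fc, `*`) +
      sweep(rows[, c1, drop = FALSE], 2, fc, `*`)
    out[, , ch] <- clip8(mixed)
  }
  out
}

# ---- connected components and contour tracing ----------------------------

# 8-connected component labels for a {0,255} mask; returns an integer
# matrix (0 = background). BFS with a vectorized frontier.
#' @keywords internal
#' @noRd
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask == 255
  labels <- matrix(0L, H, W)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  seeds <- which(fg)
  lab <- 0L
  for (s in seeds) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      c <- ((frontier - 1L) %/% H) + 1L
      nr <- rep(r, times = 8L) + rep(dr, each = length(r))
      nc <- rep(c, times = 8L) + rep(dc, each = length(r))
      ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
      idx <- (nc[ok] - 1L) * H + nr[ok]
      idx <- unique(idx[fg[idx] & labels[idx] == 0L])
      labels[idx] <- lab
      frontier <- idx
    }
  }
  labels
}

# Moore-neighbor boundary trace of one component given as a logical matrix
# (padded by one background pixel on every side). Returns an n x 2 matrix
# of 1-based (row, col) coordinates in the padded frame, clockwise.
#' @keywords internal
#' @noRd
trace_boundary <- function(comp) {
  # clockwise neighbor order starting west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  start <- which(comp, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  s <- as.integer(start)
  b0 <- s + c(0L, -1L)  # west neighbor of the start is background
  pts <- list(s)
  cur <- s; back <- b0
  max_iter <- 8L * sum(comp) + 8L
  for (iter in seq_len(max_iter)) {
    rel <- back - cur
    i <- which(dr == rel[1] & dc == rel[2])
    moved <- FALSE
    for (step in 1:8) {
      j <- ((i - 1L + step) %% 8L) + 1L
      cand <- cur + c(dr[j], dc[j])
      if (comp[cand[1], cand[2]]) {
        jprev <- ((i - 1L + step - 1L) %% 8L) + 1L
        back <- cur + c(dr[jprev], dc[jprev])
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # isolated pixel
    if (all(cur == s) && all(back == b0)) break
    pts[[length(pts) + 1L]] <- cur
  }
  do.call(rbind, pts)
}

#' Extract contours from a binary mask
#'
#' Finds the 8-connected white components of the mask and traces the outer
#' boundary of each (Moore neighbor following, clockwise); interior holes
#' are ignored. A contour records its ordered boundary points as 0-based
#' (row, col) coordinates, its area as the number of component pixels, and
#' its bounding box. Contours are sorted by area, largest first, with ties
#' broken by bounding-box (top, left).
#'
#' @param mask H x W binary mask over {0, 255}.
#' @param min_area Drop components with fewer pixels than this (default 0,
#'   keep all).
#' @return A list of contours; each is a list with elements `points`
#'   (n x 2 matrix), `area` and `bbox` (`c(top, left, height, width)`,
#'   0-based top/left).
#' @export
find_contours <- function(mask, min_area = 0) {
  assert_binary_mask(mask)
  labels <- label_components(mask)
  n <- max(labels)
  if (n == 0L) return(list())
  contours <- vector("list", n)
  for (lab in seq_len(n)) {
    px <- which(labels == lab, arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area) next
    rmin <- min(px[, 1]); rmax <- max(px[, 1])
    cmin <- min(px[, 2]); cmax <- max(px[, 2])
    comp <- matrix(FALSE, rmax - rmin + 3L, cmax - cmin + 3L)
    comp[cbind(px[, 1] - rmin + 2L, px[, 2] - cmin + 2L)] <- TRUE
    pts <- trace_boundary(comp)
    pts <- cbind(pts[, 1] + rmin - 3L, pts[, 2] + cmin - 3L)  # 0-based
    colnames(pts) <- c("row", "col")
    contours[[lab]] <- list(
      points = pts,
      area = area,
      bbox = c(top = rmin - 1L, left = cmin - 1L,
               height = rmax - rmin + 1L, width = cmax - cmin + 1L)
    )
  }
  contours <- Filter(Negate(is.null), contours)
  if (!length(contours)) return(list())
  ord <- order(-vapply(contours, `[[`, 0, "area"),
               vapply(contours, function(ct) ct$bbox["top"], 0),
               vapply(contours, function(ct) ct$bbox["left"], 0))
  contours[ord]
}

#' Draw contour boundaries onto an image
#'
#' Paints each contour's boundary pixels in the given color on a copy of
#' the image; later contours overpaint earlier ones on shared pixels. The
#' input image is left untouched.
#'
#' @param image H x W x 3 RGB array.
#' @param contours List of contours from [find_contours()].
#' @param color Length-3 RGB triple in [0, 255]; default bright green.
#' @return A painted copy of the image.
#' @export
draw_contours <- function(image, contours, color = c(0, 255, 0)) {
  assert_rgb_image(image)
  stopifnot(length(color) == 3, all(color >= 0), all(color <= 255))
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- image
  for (ct in contours) {
    pts <- ct$points
    if (any(pts[, 1] < 0) || any(pts[, 1] >= H) ||
        any(pts[, 2] < 0) || any(pts[, 2] >= W))
      stop("contour points fall outside the image", call. = FALSE)
    for (ch in 1:3)
      out[cbind(pts[, 1] + 1L, pts[, 2] + 1L, ch)] <- color[ch]
  }
  out
}

# ---- pipeline ------------------------------------------------------------

#' Segmentation pipeline configuration
#'
#' Bundles every tunable of the blast segmentation pipeline with its
#' default. Defaults: blur `sigma` 2 px with kernel radius `ceiling(3 *
#' sigma)`; hue band 250-340 degrees with saturation floor 0.25 and value
#' floor 0.15; 5 x 5 structuring element; binary threshold at 127; minimum
#' contour area 0.1 percent of the image area; maximum display dimension
#' 1024 px; green contour color. `extra_dilate` appends one more dilation
#' after the opening (off by default).
#'
#' @param sigma,kernel_radius Gaussian blur parameters (pixels).
#' @param hue_lower,hue_upper,sat_min,val_min Hue mask parameters; see
#'   [hue_range()].
#' @param se_size Structuring element side (odd).
#' @param threshold_lo Binary threshold midtone point.
#' @param min_area_frac Minimum contour area as a fraction of H * W.
#' @param resize_max Maximum image dimension before processing.
#' @param contour_color RGB triple for drawn contours.
#' @param extra_dilate Apply one additional dilation after opening.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(sigma = 2, kernel_radius = ceiling(3 * sigma),
                            hue_lower = 250, hue_upper = 340,
                            sat_min = 0.25, val_min = 0.15,
                            se_size = 5, threshold_lo = 127,
                            min_area_frac = 0.001, resize_max = 1024,
                            contour_color = c(0, 255, 0),
                            extra_dilate = FALSE) {
  cfg <- list(sigma = sigma, kernel_radius = as.integer(kernel_radius),
              hue_lower = hue_lower, hue_upper = hue_upper,
              sat_min = sat_min, val_min = val_min,
              se_size = as.integer(se_size),
              threshold_lo = threshold_lo,
              min_area_frac = min_area_frac,
              resize_max = as.integer(resize_max),
              contour_color = as.numeric(contour_color),
              extra_dilate = isTRUE(extra_dilate))
  # constructor-level validation; stages re-validate their own inputs
  stopifnot(cfg$sigma > 0, cfg$kernel_radius >= 1,
            cfg$min_area_frac >= 0, cfg$resize_max >= 64,
            length(cfg$contour_color) == 3)
  hue_range(cfg$hue_lower, cfg$hue_upper, cfg$sat_min, cfg$val_min)
  structuring_element(cfg$se_size)
  structure(cfg, class = "pipeline_config")
}

#' Run the blast segmentation pipeline on one image
#'
#' Executes, in order: bounded resize, hole filling, separable Gaussian
#' blur, RGB to HSV conversion, hue-band masking, morphological opening
#' with the configured structuring element (optionally one extra
#' dilation), fixed binary threshold, bitwise AND with the original frame,
#' contour extraction with a minimum-area filter, and contour drawing on
#' both the original and the segmented frame. All coordinates in the
#' result refer to the resized frame.
#'
#' @param image H x W x 3 RGB array (or a file path readable by
#'   [read_image()]).
#' @param config A [pipeline_config()].
#' @return An object of class `segmentation_result`: a list with `mask`
#'   (final binary mask), `contours` (area-filtered, largest first),
#'   `segmented_image` (masked original with contours drawn),
#'   `overlay_image` (original with contours drawn), `min_area` (the
#'   applied pixel floor) and `config`.
#' @examples
#' smear <- generate_smear(scene_spec(n_blasts = 1, seed = 7))
#' res <- run_pipeline(smear$image)
#' length(res$contours)
#' @export
run_pipeline <- function(image, config = pipeline_config()) {
  if (is.character(image)) image <- read_image(image)
  assert_rgb_image(image)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)

  frame <- resize_image(image, config$resize_max)
  frame <- fill_unfilled_pixels(frame)
  blurred <- gaussian_blur(frame, config$sigma, config$kernel_radius)
  hsv <- rgb_to_hsv(blurred)
  rng <- hue_range(config$hue_lower, config$hue_upper,
                   config$sat_min, config$val_min)
  mask <- hue_mask(hsv, rng)
  se <- structuring_element(config$se_size)
  mask <- remove_noise(mask, se)
  if (config$extra_dilate) mask <- dilate(mask, se)
  mask <- binary_threshold(mask, config$threshold_lo, 255)
  segmented <- bitwise_and(frame, mask)

  min_area <- config$min_area_frac * nrow(mask) * ncol(mask)
  contours <- find_contours(mask, min_area = min_area)
  overlay <- draw_contours(frame, contours, config$contour_color)
  segmented <- draw_contours(segmented, contours, config$contour_color)

  structure(list(mask = mask, contours = contours,
                 segmented_image = segmented, overlay_image = overlay,
                 min_area = min_area, config = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<segmentation_result> %d x %d frame, %d contour(s)\n",
              d[1], d[2], length(x$contours)))
  if (length(x$contours)) {
    areas <- vapply(x$contours, `[[`, 0, "area")
    cat(sprintf("  areas (px^2): %s\n", paste(areas, collapse = ", ")))
  }
  invisible(x)
}
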