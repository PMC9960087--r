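make_hsv <- function(h, s = 0.5, v = 0.5, H = 4, W = 4) {
  array(c(matrix(h, H, W), matrix(s, H, W), matrix(v, H, W)), c(H, W, 3))
}

test_that("hue mask respects the band, the floors, and wrap-around", {
  rng <- hue_range(250, 340)
  expect_true(all(hue_mask(make_hsv(300), rng) == 255))
  expect_true(all(hue_mask(make_hsv(0), rng) == 0))
  # saturation / value floors exclude pale and dark pixels
  expect_true(all(hue_mask(make_hsv(300, s = 0.1), rng) == 0))
  expect_true(all(hue_mask(make_hsv(300, v = 0.05), rng) == 0))
  # wrapped band across 360
  wrap <- hue_range(350, 10)
  expect_true(all(hue_mask(make_hsv(355), wrap) == 255))
  expect_true(all(hue_mask(make_hsv(5), wrap) == 255))
  expect_true(all(hue_mask(make_hsv(180), wrap) == 0))
  expect_error(hue_range(400, 10), "360")
})

test_that("hole filling replaces black holes with the neighborhood median", {
  # hole-free image untouched
  set.seed(31)
  img <- random_rgb(8, 8)
  img[img == 0] <- 1
  expect_identical(fill_unfilled_pixels(img), img)
  # single hole in a uniform region takes that color
  img <- array(0, c(7, 7, 3))
  img[, , 1] <- 200; img[, , 2] <- 150; img[, , 3] <- 180
  img[4, 4, ] <- 0
  out <- fill_unfilled_pixels(img)
  expect_equal(out[4, 4, ], c(200, 150, 180))
  # scattered holes in a gradient match the per-hole median oracle
  img <- array(0, c(10, 10, 3))
  for (ch in 1:3) img[, , ch] <- outer(1:10, 1:10, function(i, j) 10 * i + j + 20 * ch)
  holes <- rbind(c(3, 4), c(6, 7), c(9, 2))
  for (k in 1:3) img[holes[k, 1], holes[k, 2], ] <- 0
  out <- fill_unfilled_pixels(img)
  for (k in 1:3) {
    r <- holes[k, 1]; c <- holes[k, 2]
    for (ch in 1:3) {
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > 10 || cc < 1 || cc > 10) next
        if (all(img[rr, cc, ] == 0)) next
        nb <- c(nb, img[rr, cc, ch])
      }
      expect_equal(out[r, c, ch], floor(median(nb) + 0.5))
    }
  }
})

test_that("contour extraction matches the connected-component oracle", {
  # one solid square
  m <- matrix(0, 16, 16); m[4:13, 5:14] <- 255
  cts <- find_contours(m)
  expect_length(cts, 1)
  expect_equal(cts[[1]]$area, 100)
  expect_equal(unname(cts[[1]]$bbox), c(3, 4, 10, 10))
  expect_gte(nrow(cts[[1]]$points), 3)
  # empty mask
  expect_length(find_contours(matrix(0, 5, 5)), 0)
  # three disjoint blobs come back largest first
  m <- matrix(0, 40, 40)
  m[2:3, 2:3] <- 255                      # 4 px
  m[10:19, 30:34] <- 255                  # 50 px
  m[21:40, 1:10] <- 255                   # 200 px
  areas <- vapply(find_contours(m), `[[`, 0, "area")
  expect_equal(areas, c(200, 50, 4))
  # random masks against the label-propagation oracle
  set.seed(32)
  for (i in 1:25) {
    m <- random_mask(32, 32, p = runif(1, 0.1, 0.5))
    cts <- find_contours(m)
    ref <- oracle_components(m)
    expect_equal(length(cts), NROW(ref))
    if (length(cts)) {
      got <- t(vapply(cts, function(ct) c(ct$area, unname(ct$bbox)),
                      numeric(5)))
      expect_equal(unname(got), unname(cbind(ref[, "area"], ref[, "top"],
                                             ref[, "left"], ref[, "height"],
                                             ref[, "width"])))
      # boundary points lie inside their component's bounding box
      for (j in seq_along(cts)) {
        pts <- cts[[j]]$points
        bb <- cts[[j]]$bbox
        expect_true(all(pts[, 1] >= bb["top"] &
                        pts[, 1] < bb["top"] + bb["height"]))
        expect_true(all(pts[, 2] >= bb["left"] &
                        pts[, 2] < bb["left"] + bb["width"]))
        expect_true(all(m[(pts[, 2]) * 32 + pts[, 1] + 1] == 255))
      }
    }
  }
})

test_that("contour drawing paints exactly the boundary, last contour wins", {
  img <- array(10, c(12, 12, 3))
  expect_identical(draw_contours(img, list()), img)
  m <- matrix(0, 12, 12); m[4:9, 4:9] <- 255
  ct <- find_contours(m)
  out <- draw_contours(img, ct, c(0, 255, 0))
  painted <- out[, , 2] == 255
  # perimeter of a 6x6 square is 20 pixels
  expect_equal(sum(painted), 20)
  expect_true(all(painted[4:9, 4] & painted[4:9, 9] &
                  painted[4, 4:9] & painted[9, 4:9]))
  expect_identical(img[5, 5, ], c(10, 10, 10))  # input untouched
  # overlapping contours: the later paint overwrites
  c1 <- list(points = cbind(row = 2L, col = 2L), area = 1,
             bbox = c(top = 2, left = 2, height = 1, width = 1))
  c2 <- list(points = cbind(row = 2L, col = 2L), area = 1,
             bbox = c(top = 2, left = 2, height = 1, width = 1))
  out <- draw_contours(img, list(c1, c2), c(9, 9, 9))
  expect_equal(out[3, 3, ], c(9, 9, 9))
  bad <- list(points = cbind(row = 50L, col = 2L), area = 1,
              bbox = c(top = 50, left = 2, height = 1, width = 1))
  expect_error(draw_contours(img, list(bad)), "outside")
})

test_that("pipeline finds a generated blast and stays blank on negatives", {
  smear <- generate_smear(scene_spec(n_blasts = 1,
                                     blast_radius_range = c(40, 40),
                                     seed = 5))
  res <- run_pipeline(smear$image)
  expect_length(res$contours, 1)
  pts <- which(res$mask == 255, arr.ind = TRUE)
  centroid <- c(mean(pts[, 1]) - 1, mean(pts[, 2]) - 1)
  expect_lt(max(abs(centroid - smear$truth$blast_centroids[1, ])), 3)
  # negative smear: no contours, fully black segmentation
  neg <- generate_smear(scene_spec(n_blasts = 0, n_eosinophils = 2,
                                   seed = 6))
  resn <- run_pipeline(neg$image)
  expect_length(resn$contours, 0)
  expect_true(all(resn$segmented_image == 0))
  # degenerate all-black input
  resb <- run_pipeline(array(0, c(64, 64, 3)))
  expect_length(resb$contours, 0)
})

test_that("pipeline is deterministic and its mask traces back to the hue band", {
  smear <- generate_smear(scene_spec(n_blasts = 2, seed = 8))
  cfg <- pipeline_config()
  r1 <- run_pipeline(smear$image, cfg)
  r2 <- run_pipeline(smear$image, cfg)
  expect_identical(r1, r2)
  # provenance: final mask within one dilation of the raw hue mask
  frame <- fill_unfilled_pixels(smear$image)
  hsv <- rgb_to_hsv(gaussian_blur(frame, cfg$sigma, cfg$kernel_radius))
  raw <- hue_mask(hsv, hue_range(cfg$hue_lower, cfg$hue_upper,
                                 cfg$sat_min, cfg$val_min))
  reach <- dilate(raw, structuring_element(cfg$se_size))
  expect_true(mask_subset(r1$mask, reach))
})

test_that("contour count never increases with the minimum-area filter", {
  smear <- generate_smear(scene_spec(n_blasts = 3, n_eosinophils = 2,
                                     seed = 9))
  fracs <- c(0, 0.0005, 0.001, 0.005, 0.02)
  counts <- vapply(fracs, function(f) {
    length(run_pipeline(smear$image,
                        pipeline_config(min_area_frac = f))$contours)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("bilinear resize bounds the longest side and preserves flat fields", {
  img <- array(200, c(130, 65, 3))
  out <- resize_image(img, 64)
  expect_equal(dim(out), c(64, 32, 3))
  expect_true(all(out == 200))
  # no upscaling
  expect_identical(resize_image(img, 512), img)
})
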