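# Deterministic generator of smear-like scenes with per-image ground truth.
# Emulates a Romanowsky-stained peripheral smear: pale background, red/pink
# erythrocytes with central pallor, violet/purple blast nuclei with an
# irregular envelope and chromatin texture, orange granular eosinophils,
# specular reflections and sensor noise.

# run `code` under a temporary RNG state seeded with `seed`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# numeric HSV -> RGB (h in degrees, s and v in [0,1]); returns n x 3 in
# [0,255]. Used only for painting synthetic scenes, keeping the analysis
# path's rgb_to_hsv() independent of it.
#' @keywords internal
#' @noRd
hsv_to_rgb_num <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    m <- i == k
    if (!any(m)) next
    rgb <- switch(as.character(k),
                  "0" = list(v, t, p), "1" = list(q, v, p),
                  "2" = list(p, v, t), "3" = list(p, q, v),
                  "4" = list(t, p, v), "5" = list(v, p, q))
    r[m] <- rgb[[1]][m]; g[m] <- rgb[[2]][m]; b[m] <- rgb[[3]][m]
  }
  cbind(r, g, b) * 255
}

#' Specification of a synthetic smear scene
#'
#' Defaults describe a realistic 256 x 256 field of view: 35 erythrocytes
#' (hue wrapping the red boundary, 340-20 degrees), blasts of 22-40 px
#' radius in the violet band (260-320 degrees), one orange eosinophil
#' distractor (20-40 degrees), additive Gaussian pixel noise of 3
#' intensity levels and 2 bright specular spots.
#'
#' @param width,height Scene dimensions in pixels (at least 64).
#' @param n_blasts Number of blast cells; the ground-truth label is 1 iff
#'   this is positive.
#' @param blast_radius_range Min/max blast base radius in pixels.
#' @param blast_hue_range Hue band for blast nuclei, degrees.
#' @param n_erythrocytes Number of red cells.
#' @param erythrocyte_hue_range Hue band for red cells; wraps across 360
#'   when the first bound exceeds the second.
#' @param n_eosinophils Number of eosinophil distractors.
#' @param eosinophil_hue_range Hue band for eosinophils, degrees.
#' @param noise_sd Additive Gaussian noise standard deviation, intensity
#'   levels.
#' @param n_specular Number of near-white reflection spots.
#' @param seed Integer seed; scenes are bitwise reproducible from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256, height = 256,
                       n_blasts = 1, blast_radius_range = c(22, 40),
                       blast_hue_range = c(260, 320),
                       n_erythrocytes = 35,
                       erythrocyte_hue_range = c(340, 20),
                       n_eosinophils = 1,
                       eosinophil_hue_range = c(20, 40),
                       noise_sd = 3, n_specular = 2, seed = 1) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_blasts = as.integer(n_blasts),
               blast_radius_range = as.numeric(blast_radius_range),
               blast_hue_range = as.numeric(blast_hue_range),
               n_erythrocytes = as.integer(n_erythrocytes),
               erythrocyte_hue_range = as.numeric(erythrocyte_hue_range),
               n_eosinophils = as.integer(n_eosinophils),
               eosinophil_hue_range = as.numeric(eosinophil_hue_range),
               noise_sd = as.numeric(noise_sd),
               n_specular = as.integer(n_specular),
               seed = as.integer(seed))
  stopifnot(spec$width >= 64, spec$height >= 64,
            spec$n_blasts >= 0, spec$n_erythrocytes >= 0,
            spec$n_eosinophils >= 0, spec$n_specular >= 0,
            all(spec$blast_radius_range > 0),
            spec$blast_radius_range[1] <= spec$blast_radius_range[2],
            spec$noise_sd >= 0)
  structure(spec, class = "scene_spec")
}

#' @keywords internal
#' @noRd
sample_hue <- function(range) {
  lo <- range[1]; hi <- range[2]
  if (lo <= hi) stats::runif(1, lo, hi)
  else (lo + stats::runif(1, 0, (360 - lo) + hi)) %% 360
}

#' Generate one synthetic smear with ground truth
#'
#' Paints, in order, background with gentle illumination drift,
#' erythrocytes (anti-aliased discs with a paler center), eosinophils
#' (granular orange discs), blasts (radially perturbed polygons — a 3-7
#' harmonic sinusoidal deformation of a disc — with darker chromatin
#' speckle), then specular highlights and additive Gaussian noise. The
#' ground-truth mask is the union of blast interiors; blasts that cannot
#' be placed fully inside the frame raise an error.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (H x W x 3 RGB array) and `truth` (list
#'   with `blast_mask` over {0,255}, `label` 0/1 and `blast_centroids`,
#'   an n x 2 matrix of 0-based (row, col) centers).
#' @examples
#' smear <- generate_smear(scene_spec(n_blasts = 0, seed = 7))
#' smear$truth$label  # 0
#' @export
generate_smear <- function(spec = scene_spec()) {
  if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)

    # pale, slightly lavender background with low-frequency illumination
    base <- hsv_to_rgb_num(272, 0.05, 0.92)
    illum <- 1 + 0.02 * sin(2 * pi * rows / H + stats::runif(1, 0, 2 * pi)) *
      cos(2 * pi * cols / W + stats::runif(1, 0, 2 * pi))
    canvas <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) canvas[, , ch] <- base[ch] * illum

    blend_disc <- function(center, radius, hue, sat, val,
                           pallor = 0, jitter_val = NULL) {
      r0 <- max(1L, floor(center[1] - radius - 1))
      r1 <- min(H, ceiling(center[1] + radius + 1))
      c0 <- max(1L, floor(center[2] - radius - 1))
      c1 <- min(W, ceiling(center[2] + radius + 1))
      rr <- rows[r0:r1, c0:c1]; cc <- cols[r0:r1, c0:c1]
      d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
      cov <- pmin(pmax(radius - d + 0.5, 0), 1)
      if (all(cov == 0)) return(invisible())
      v <- matrix(val, nrow(d), ncol(d))
      if (pallor > 0)
        v <- v * (1 + pallor * exp(-(d / (0.45 * radius))^2))
      if (!is.null(jitter_val))
        v <- v * matrix(stats::runif(length(d), jitter_val[1],
                                     jitter_val[2]), nrow(d))
      v <- pmin(v, 0.98)
      obj <- hsv_to_rgb_num(rep(hue, length(d)), rep(sat, length(d)),
                            as.vector(v))
      for (ch in 1:3) {
        patch <- canvas[r0:r1, c0:c1, ch]
        canvas[r0:r1, c0:c1, ch] <<-
          (1 - cov) * patch + cov * matrix(obj[, ch], nrow(d))
      }
      invisible()
    }

    for (i in seq_len(spec$n_erythrocytes)) {
      blend_disc(center = c(stats::runif(1, 1, H), stats::runif(1, 1, W)),
                 radius = stats::runif(1, 10, 16),
                 hue = sample_hue(spec$erythrocyte_hue_range),
                 sat = stats::runif(1, 0.30, 0.45),
                 val = stats::runif(1, 0.60, 0.72),
                 pallor = 0.15)
    }

    for (i in seq_len(spec$n_eosinophils)) {
      blend_disc(center = c(stats::runif(1, 1, H), stats::runif(1, 1, W)),
                 radius = stats::runif(1, 14, 20),
                 hue = sample_hue(spec$eosinophil_hue_range),
                 sat = stats::runif(1, 0.45, 0.60),
                 val = stats::runif(1, 0.55, 0.65),
                 jitter_val = c(0.85, 1.15))
    }

    blast_mask <- matrix(0, H, W)
    centroids <- NULL
    for (i in seq_len(spec$n_blasts)) {
      r0b <- stats::runif(1, spec$blast_radius_range[1],
                          spec$blast_radius_range[2])
      margin <- r0b * 1.35 + 2
      if (2 * margin >= H || 2 * margin >= W)
        stop("blast radius too large for the frame", call. = FALSE)
      center <- c(stats::runif(1, margin, H - margin),
                  stats::runif(1, margin, W - margin))
      amp <- stats::runif(5, 0, 0.055)
      phase <- stats::runif(5, 0, 2 * pi)
      rmax <- r0b * (1 + sum(amp))
      rlo <- max(1L, floor(center[1] - rmax - 1))
      rhi <- min(H, ceiling(center[1] + rmax + 1))
      clo <- max(1L, floor(center[2] - rmax - 1))
      chi <- min(W, ceiling(center[2] + rmax + 1))
      rr <- rows[rlo:rhi, clo:chi]; cc <- cols[rlo:rhi, clo:chi]
      d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
      theta <- atan2(rr - center[1], cc - center[2])
      redge <- r0b * (1 + Reduce(`+`, lapply(1:5, function(k)
        amp[k] * sin((k + 2) * theta + phase[k]))))
      cov <- pmin(pmax(redge - d + 0.5, 0), 1)
      hue <- sample_hue(spec$blast_hue_range)
      sat <- stats::runif(1, 0.55, 0.75)
      val <- stats::runif(1, 0.42, 0.58)
      vmat <- val * matrix(stats::runif(length(d), 0.78, 1), nrow(d))
      obj <- hsv_to_rgb_num(rep(hue, length(d)), rep(sat, length(d)),
                            as.vector(vmat))
      for (ch in 1:3) {
        patch <- canvas[rlo:rhi, clo:chi, ch]
        canvas[rlo:rhi, clo:chi, ch] <-
          (1 - cov) * patch + cov * matrix(obj[, ch], nrow(d))
      }
      inside <- cov >= 0.5
      patchm <- blast_mask[rlo:rhi, clo:chi]
      patchm[inside] <- 255
      blast_mask[rlo:rhi, clo:chi] <- patchm
      px <- which(inside, arr.ind = TRUE)
      centroids <- rbind(centroids,
                         c(mean(px[, 1]) + rlo - 2, mean(px[, 2]) + clo - 2))
    }

    for (i in seq_len(spec$n_specular)) {
      ctr <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      rad <- stats::runif(1, 3, 6)
      d <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
      wgt <- exp(-(d / rad)^2)
      white <- c(252, 251, 253)
      for (ch in 1:3)
        canvas[, , ch] <- (1 - wgt) * canvas[, , ch] + wgt * white[ch]
    }

    if (spec$noise_sd > 0)
      canvas <- canvas + array(stats::rnorm(length(canvas), 0,
                                            spec$noise_sd), dim(canvas))
    image <- array(clip8(canvas), dim = dim(canvas))

    list(image = image,
         truth = list(blast_mask = blast_mask,
                      label = as.integer(spec$n_blasts > 0),
                      blast_centroids = centroids))
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes positive scenes as `Im001_1.png`, `Im002_1.png`, ... and
#' negative scenes as `Im101_0.png`, ... (the trailing digit encodes the
#' ground-truth label), together with `*_mask.png` ground-truth masks and
#' a `manifest.csv` (filename, label, n_blasts, seed). Positive scenes
#' carry 1-3 blasts; every scene may carry 0-2 eosinophil distractors.
#' Fully reproducible from `seed`. Negative numbering starts at 101, so
#' `n_pos` beyond 100 would collide; keep `n_pos <= 100`.
#'
#' @param n_pos,n_neg Number of positive / negative images.
#' @param out_dir Output directory, created if needed.
#' @param seed Integer master seed.
#' @param ... Overrides passed on to [scene_spec()] (e.g. `width`,
#'   `noise_sd`).
#' @return The manifest as a data.frame (invisibly).
#' @export
generate_dataset <- function(n_pos, n_neg, out_dir, seed = 42, ...) {
  if (n_pos + n_neg < 1) stop("need at least one image", call. = FALSE)
  if (n_pos > 100) stop("n_pos must be <= 100 (negative numbering starts at 101)",
                        call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create `out_dir`", call. = FALSE)
  n <- n_pos + n_neg
  plan <- with_seed(seed, data.frame(
    idx = c(seq_len(n_pos), 100 + seq_len(n_neg)),
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    n_blasts = c(sample(1:3, n_pos, replace = TRUE), rep(0L, n_neg)),
    n_eos = sample(0:2, n, replace = TRUE),
    seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  plan$filename <- sprintf("Im%03d_%d.png", plan$idx, plan$label)
  overrides <- list(...)
  for (k in seq_len(n)) {
    args <- c(list(n_blasts = plan$n_blasts[k], n_eosinophils = plan$n_eos[k],
                   seed = plan$seed[k]), overrides)
    smear <- generate_smear(do.call(scene_spec, args))
    write_image(smear$image, file.path(out_dir, plan$filename[k]))
    write_mask(smear$truth$blast_mask,
               file.path(out_dir, sub("\\.png$", "_mask.png",
                                      plan$filename[k])))
  }
  manifest <- plan[, c("filename", "label", "n_blasts", "seed")]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
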