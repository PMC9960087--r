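# Independent brute-force oracles, deliberately coded without reusing the
# package's vectorized paths.

# direct 2-D convolution with an explicit K x K kernel, replicate border
oracle_conv2d <- function(m, k2d) {
  r <- (nrow(k2d) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  ridx <- c(rep(1L, r), seq_len(H), rep(H, r))
  cidx <- c(rep(1L, r), seq_len(W), rep(W, r))
  padded <- m[ridx, cidx]
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(k2d))) {
    for (j in seq_len(ncol(k2d))) {
      out <- out + k2d[i, j] * padded[i:(i + H - 1L), j:(j + W - 1L)]
    }
  }
  pmin(pmax(floor(out + 0.5), 0), 255)
}

# per-pixel erosion fit test, out-of-image treated as background
oracle_erode <- function(mask, se_shape) {
  H <- nrow(mask); W <- ncol(mask)
  r <- (nrow(se_shape) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (x in seq_len(H)) {
    for (y in seq_len(W)) {
      fits <- TRUE
      for (i in seq_len(nrow(se_shape))) {
        for (j in seq_len(ncol(se_shape))) {
          if (se_shape[i, j] == 0) next
          px <- x + i - r - 1L; py <- y + j - r - 1L
          if (px < 1L || px > H || py < 1L || py > W ||
              mask[px, py] != 255) {
            fits <- FALSE
            break
          }
        }
        if (!fits) break
      }
      if (fits) out[x, y] <- 255
    }
  }
  out
}

# 8-connected component labeling by iterated min-label propagation
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask == 255
  lab <- matrix(0L, H, W)
  lab[fg] <- which(fg)
  repeat {
    big <- matrix(Inf, H + 2L, W + 2L)
    big[2:(H + 1L), 2:(W + 1L)][fg] <- lab[fg]
    nxt <- lab
    for (dr in -1:1) {
      for (dc in -1:1) {
        shifted <- big[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
        sel <- fg & is.finite(shifted) & shifted < nxt
        nxt[sel] <- shifted[sel]
      }
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}

# summary of components as a sorted table of (area, top, left)
oracle_components <- function(mask) {
  lab <- oracle_label(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  comp <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    c(area = nrow(px), top = min(px[, 1]) - 1L, left = min(px[, 2]) - 1L,
      height = max(px[, 1]) - min(px[, 1]) + 1L,
      width = max(px[, 2]) - min(px[, 2]) + 1L)
  })
  out <- do.call(rbind, comp)
  if (is.null(out)) return(out)
  out[order(-out[, "area"], out[, "top"], out[, "left"]), , drop = FALSE]
}

random_mask <- function(H, W, p = 0.4) {
  matrix(sample(c(0, 255), H * W, replace = TRUE, prob = c(1 - p, p)), H, W)
}

random_rgb <- function(H, W) {
  array(as.numeric(sample(0:255, H * W * 3, replace = TRUE)),
        dim = c(H, W, 3))
}

# duality oracle: complement-erode-complement computed on a background-
# padded embedding so the finite frame behaves like the infinite plane
oracle_dual_dilate <- function(m, se) {
  r <- (se$size - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  emb <- matrix(0, H + 2L * r, W + 2L * r)
  emb[(r + 1L):(r + H), (r + 1L):(r + W)] <- m
  full <- 255 - erode(255 - emb, se)
  full[(r + 1L):(r + H), (r + 1L):(r + W)]
}

mask_subset <- function(a, b) all(b[a == 255] == 255)
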