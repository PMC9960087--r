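# Raster I/O, dataset indexing and result export.

#' Read an 8-bit raster image
#'
#' PNG and TIFF are read natively (png/tiff packages); JPEG is read
#' through EBImage when that package is installed. Grayscale inputs are
#' replicated to three channels and an alpha channel, if present, is
#' dropped.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return H x W x 3 RGB array with values in [0, 255].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the 'EBImage' package", call. = FALSE)
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 2L) raw <- array(rep(raw[, , 1], 3), c(dim(raw)[1:2], 3L))
  out <- clip8(raw * 255)
  dim(out) <- c(dim(raw)[1:2], 3L)
  out
}

#' Write an RGB image as PNG
#'
#' @param image H x W x 3 RGB array in [0, 255].
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a binary mask as a grayscale PNG
#'
#' @param mask H x W matrix over {0, 255}.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_binary_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a binary mask from a grayscale PNG
#'
#' @param path Path to a PNG written by [write_mask()].
#' @return H x W matrix over {0, 255}.
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  (raw > 0.5) * 255
}

# ---- dataset indexing ----------------------------------------------------

IMAGE_EXTS <- c("png", "jpg", "jpeg", "tif", "tiff", "bmp")

#' Index an image directory with per-image labels
#'
#' In `suffix` mode the ground-truth label is parsed from the trailing
#' digit of the file name before the extension, with or without an
#' underscore (`Im001_1.png` and `Im0011.png` both carry label 1) — the
#' ALL-IDB1 convention where 0 marks non-cancerous and 1 cancerous
#' images. Non-conforming image names get a warning and an NA label.
#' `manifest` mode reads labels from a `manifest.csv` (columns filename,
#' label); `none` leaves all labels NA. Ground-truth `*_mask.png` files
#' and non-image files are skipped.
#'
#' @param dir Directory of images.
#' @param label_mode One of "suffix", "manifest", "none".
#' @param manifest Manifest file name for `manifest` mode.
#' @return A data.frame with columns `path`, `image_id`, `label`, sorted
#'   by `image_id`.
#' @export
load_dataset <- function(dir, label_mode = c("suffix", "manifest", "none"),
                         manifest = "manifest.csv") {
  label_mode <- match.arg(label_mode)
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, full.names = TRUE)
  is_img <- tolower(tools::file_ext(files)) %in% IMAGE_EXTS
  skipped <- files[!is_img & !dir.exists(files)]
  for (f in skipped) message("skipping non-image file: ", basename(f))
  files <- files[is_img]
  files <- files[!grepl("_mask\\.[^.]+$", basename(files))]
  if (!length(files))
    return(data.frame(path = character(), image_id = character(),
                      label = integer(), stringsAsFactors = FALSE))
  image_id <- sub("\\.[^.]+$", "", basename(files))
  label <- rep(NA_integer_, length(files))
  if (label_mode == "suffix") {
    m <- regmatches(image_id, regexpr("[01]$", image_id))
    ok <- grepl("[01]$", image_id)
    label[ok] <- as.integer(m)
    for (f in basename(files)[!ok])
      warning("no trailing 0/1 label digit in: ", f, call. = FALSE)
  } else if (label_mode == "manifest") {
    mf <- file.path(dir, manifest)
    if (!file.exists(mf)) stop("manifest not found: ", mf, call. = FALSE)
    man <- utils::read.csv(mf, stringsAsFactors = FALSE)
    label <- man$label[match(basename(files), man$filename)]
  }
  idx <- data.frame(path = files, image_id = image_id,
                    label = as.integer(label), stringsAsFactors = FALSE)
  idx[order(idx$image_id), , drop = FALSE]
}

#' Segment, classify and score every labeled image in a directory
#'
#' Composes [load_dataset()], [run_pipeline()], [classify()],
#' [confusion_matrix()] and [compute_metrics()].
#'
#' @param dir Image directory.
#' @param config A [pipeline_config()].
#' @param min_blast_area Optional classifier area floor.
#' @param label_mode Passed to [load_dataset()].
#' @return A list with `predictions` (data.frame), `cm`
#'   (`confusion_matrix`, NULL when no labels are known) and `metrics`
#'   (`metric_report` or NULL).
#' @export
evaluate_dataset <- function(dir, config = pipeline_config(),
                             min_blast_area = NULL,
                             label_mode = "suffix") {
  idx <- load_dataset(dir, label_mode)
  if (!nrow(idx)) stop("no images found in ", dir, call. = FALSE)
  preds <- lapply(seq_len(nrow(idx)), function(i) {
    res <- run_pipeline(read_image(idx$path[i]), config)
    classify(res, min_blast_area, image_id = idx$image_id[i])
  })
  tab <- predictions_table(preds, idx$label)
  cm <- metrics <- NULL
  if (!anyNA(idx$label) && nrow(idx) >= 1) {
    cm <- confusion_matrix(tab$pred_label, idx$label)
    metrics <- compute_metrics(cm)
  }
  list(predictions = tab, cm = cm, metrics = metrics)
}

# ---- configuration files -------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- contour export ------------------------------------------------------

#' Tabulate contours
#'
#' @param contours List of contours from [find_contours()].
#' @param image_id Identifier repeated in the first column.
#' @return data.frame(image_id, contour_id, area, top, left, height,
#'   width).
#' @export
contours_table <- function(contours, image_id = NA_character_) {
  if (!length(contours))
    return(data.frame(image_id = character(), contour_id = integer(),
                      area = numeric(), top = integer(), left = integer(),
                      height = integer(), width = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    image_id = image_id,
    contour_id = seq_along(contours),
    area = vapply(contours, `[[`, 0, "area"),
    top = vapply(contours, function(ct) ct$bbox[["top"]], 0),
    left = vapply(contours, function(ct) ct$bbox[["left"]], 0),
    height = vapply(contours, function(ct) ct$bbox[["height"]], 0),
    width = vapply(contours, function(ct) ct$bbox[["width"]], 0),
    stringsAsFactors = FALSE
  )
}

#' Export contours as GeoJSON-style polygons
#'
#' Each contour becomes a Feature whose Polygon ring lists [col, row]
#' coordinates (x, y order, 0-based) with the ring closed.
#'
#' @param contours List of contours from [find_contours()].
#' @param path Optional output file; when NULL the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
contours_to_geojson <- function(contours, path = NULL) {
  features <- lapply(seq_along(contours), function(i) {
    pts <- contours[[i]]$points
    ring <- cbind(pts[, 2], pts[, 1])
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(contour_id = i, area = contours[[i]]$area),
         geometry = list(type = "Polygon",
                         coordinates = list(ring)))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection",
                                features = features),
                           auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
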