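# Image-level call: an image is cancerous when segmentation found at least
# one sufficiently large contour.

#' Classify a segmentation result as cancerous or non-cancerous
#'
#' The decision rule is contour presence with an area floor: the image is
#' labeled cancerous (1) when at least one contour has area at least
#' `min_blast_area`, and non-cancerous (0) otherwise. By default the floor
#' equals the pipeline's own minimum-area filter, so any surviving contour
#' triggers a positive call; raising the floor lets a user discount small
#' contoured distractors (for example eosinophils, which are normal white
#' cells that can pick up a borderline stain hue) without re-running the
#' segmentation.
#'
#' @param result A `segmentation_result` from [run_pipeline()].
#' @param min_blast_area Minimum contour area in pixels squared for a
#'   positive call; defaults to the area filter already applied by the
#'   pipeline.
#' @param image_id Optional identifier recorded in the prediction.
#' @return An object of class `prediction`: a list with `label` (0/1),
#'   `n_contours`, `largest_area` and `image_id`.
#' @examples
#' smear <- generate_smear(scene_spec(n_blasts = 0, seed = 3))
#' classify(run_pipeline(smear$image))$label  # 0: nothing to contour
#' @export
classify <- function(result, min_blast_area = NULL, image_id = NA_character_) {
  if (!inherits(result, "segmentation_result"))
    stop("`result` must come from run_pipeline()", call. = FALSE)
  if (is.null(min_blast_area)) min_blast_area <- result$min_area
  areas <- vapply(result$contours, `[[`, 0, "area")
  largest <- if (length(areas)) max(areas) else 0
  structure(list(
    label = as.integer(length(areas) > 0 && largest >= min_blast_area),
    n_contours = length(areas),
    largest_area = largest,
    image_id = image_id
  ), class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("<prediction> %s: %s (%d contour(s), largest %g px^2)\n",
              ifelse(is.na(x$image_id), "image", x$image_id),
              ifelse(x$label == 1, "cancerous", "non-cancerous"),
              x$n_contours, x$largest_area))
  invisible(x)
}

#' Collect predictions into a data frame
#'
#' @param predictions List of `prediction` objects.
#' @param truths Optional vector of true labels (0/1 or NA), recycled
#'   checks apply.
#' @return A data.frame with columns image_id, true_label, pred_label,
#'   n_contours, largest_area.
#' @export
predictions_table <- function(predictions, truths = NULL) {
  if (is.null(truths)) truths <- rep(NA_integer_, length(predictions))
  if (length(truths) != length(predictions))
    stop("`truths` length must match `predictions`", call. = FALSE)
  data.frame(
    image_id = vapply(predictions, `[[`, "", "image_id"),
    true_label = as.integer(truths),
    pred_label = vapply(predictions, function(p) as.integer(p$label), 0L),
    n_contours = vapply(predictions, function(p) as.integer(p$n_contours), 0L),
    largest_area = vapply(predictions, `[[`, 0, "largest_area"),
    stringsAsFactors = FALSE
  )
}
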