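# Confusion-matrix bookkeeping and the five standard performance measures.

#' Build a confusion matrix from paired labels
#'
#' The positive class is "cancerous" (1). `preds` may be a vector of 0/1
#' labels, a list of `prediction` objects, or a data frame from
#' [predictions_table()].
#'
#' @param preds Predicted labels.
#' @param truths True labels, same length, each 0 or 1.
#' @return An object of class `confusion_matrix`: a list with counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @examples
#' confusion_matrix(c(1, 1, 0), c(1, 1, 0))
#' @export
confusion_matrix <- function(preds, truths) {
  if (is.data.frame(preds)) preds <- preds$pred_label
  if (is.list(preds)) preds <- vapply(preds, `[[`, 0L, "label")
  preds <- as.integer(preds); truths <- as.integer(truths)
  if (length(preds) != length(truths))
    stop("`preds` and `truths` must have equal length", call. = FALSE)
  if (length(preds) < 1L)
    stop("at least one (pred, truth) pair is required", call. = FALSE)
  if (anyNA(preds) || anyNA(truths) ||
      !all(preds %in% 0:1) || !all(truths %in% 0:1))
    stop("labels must all be 0 or 1", call. = FALSE)
  structure(list(
    tp = sum(preds == 1L & truths == 1L),
    fp = sum(preds == 1L & truths == 0L),
    tn = sum(preds == 0L & truths == 0L),
    fn = sum(preds == 0L & truths == 1L)
  ), class = "confusion_matrix")
}

#' Assemble a confusion matrix directly from counts
#'
#' Convenience constructor for scoring printed 2 x 2 tables.
#'
#' @param tp,fp,tn,fn Non-negative image counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("the confusion matrix must contain at least one image",
         call. = FALSE)
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], tn = counts[3],
                 fn = counts[4]), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(`actual` = c("0", "1"),
                              `predicted` = c("0", "1")))
  print(m)
  invisible(x)
}

#' Compute the five performance measures from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the F-measure (harmonic mean
#' of precision and recall). A measure whose denominator is zero is
#' undefined: it is reported as `NA` and listed in the report's
#' `undefined` field rather than silently set to 0.
#'
#' @param cm A `confusion_matrix`.
#' @return An object of class `metric_report`: proportions in [0, 1] (or
#'   NA), plus the source counts and the names of undefined measures.
#' @examples
#' compute_metrics(confusion_counts(tp = 40, fp = 3, tn = 38, fn = 0))
#' @export
compute_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix"))
    stop("`cm` must be a confusion_matrix", call. = FALSE)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f_measure <- if (!is.na(precision) && !is.na(recall) &&
                   precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  metrics <- list(
    accuracy = safe_div(tp + tn, total),
    precision = precision,
    recall = recall,
    specificity = safe_div(tn, tn + fp),
    f_measure = f_measure
  )
  undefined <- names(metrics)[vapply(metrics, is.na, TRUE)]
  structure(c(metrics,
              list(counts = cm, undefined = undefined)),
            class = "metric_report")
}

# Percentage with 2 decimals, rounding half away from zero (the convention
# used when quoting e.g. 96.30%). The epsilon guards against binary
# representation pushing an exact half below .5.
#' @keywords internal
#' @noRd
format_pct <- function(x, digits = 2) {
  if (is.na(x)) return("undefined")
  scaled <- x * 100 * 10^digits
  rounded <- sign(scaled) * floor(abs(scaled) + 0.5 + 1e-9) / 10^digits
  sprintf(paste0("%.", digits, "f%%"), rounded)
}

#' Percentage value of a metric, rounded as printed
#'
#' @param x A proportion in [0, 1] (or NA).
#' @param digits Decimal places (default 2).
#' @return Numeric percentage rounded half-away-from-zero, NA if undefined.
#' @export
metric_percent <- function(x, digits = 2) {
  if (is.na(x)) return(NA_real_)
  sign(x) * floor(abs(x) * 100 * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Performance measures\n")
  for (nm in c("accuracy", "precision", "recall", "specificity",
               "f_measure")) {
    label <- c(accuracy = "Accuracy", precision = "Precision score",
               recall = "Recall Score", specificity = "Specificity",
               f_measure = "F-measure")[[nm]]
    cat(sprintf("  %-16s %s\n", label, format_pct(x[[nm]])))
  }
  if (length(x$undefined))
    cat("  (undefined: ", paste(x$undefined, collapse = ", "),
        " — zero denominator)\n", sep = "")
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' Percentages are written unrounded (full double precision) together with
#' the source counts and the undefined-measure flags.
#'
#' @param report A `metric_report`.
#' @param path Optional file to write; when NULL the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
metrics_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  payload <- list(
    counts = report$counts[c("tp", "fp", "tn", "fn")],
    percent = lapply(report[c("accuracy", "precision", "recall",
                              "specificity", "f_measure")],
                     function(v) if (is.na(v)) NULL else v * 100),
    undefined = as.list(report$undefined)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
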