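#' Confusion matrix for fall detection
#'
#' Counts with `fall` as the positive class.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (n=%d, positive = fall)\n",
    x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn
  ))
  invisible(x)
}

#' Count prediction outcomes against labels
#'
#' @param predictions,labels Equal-length vectors with values `"fall"` /
#'   `"not_fall"`.
#' @return A [confusion_matrix()] (positive class: fall).
#' @export
evaluate_predictions <- function(predictions, labels) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) {
    stop(
      "length mismatch: ", length(predictions), " predictions vs ",
      length(labels), " labels"
    )
  }
  bad <- setdiff(unique(c(predictions, labels)), c("fall", "not_fall"))
  if (length(bad)) stop("values outside {fall, not_fall}: ", toString(bad))
  confusion_matrix(
    tp = sum(predictions == "fall" & labels == "fall"),
    fp = sum(predictions == "fall" & labels == "not_fall"),
    tn = sum(predictions == "not_fall" & labels == "not_fall"),
    fn = sum(predictions == "not_fall" & labels == "fall")
  )
}

#' Performance metrics from a confusion matrix
#'
#' The five standard fall-detection metrics, in percent:
#' accuracy `100 (tp+tn) / n`, sensitivity (fall recall) `100 tp / (tp+fn)`,
#' specificity `100 tn / (tn+fp)`, precision (positive predictive value)
#' `100 tp / (tp+fp)` and F1-score, the harmonic mean of precision and
#' sensitivity. A metric with a zero denominator is reported as `NA` and
#' flagged in the `undefined` attribute rather than raising an error.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report`: named numeric vector with
#'   elements `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`
#'   (full precision; the print method rounds to 2 decimals, half-up).
#' @examples
#' compute_metrics(confusion_matrix(tp = 69, fp = 0, tn = 70, fn = 1))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  accuracy <- ratio(cm$tp + cm$tn, n)
  sensitivity <- ratio(cm$tp, cm$tp + cm$fn)
  specificity <- ratio(cm$tn, cm$tn + cm$fp)
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
    (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else {
    NA_real_
  }
  m <- c(
    accuracy = accuracy, sensitivity = sensitivity,
    specificity = specificity, precision = precision, f1 = f1
  )
  structure(m,
    class = "metrics_report",
    undefined = names(m)[is.na(m)],
    confusion = cm
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- round_half_up(unclass(x), 2)
  cat("<metrics_report> (%, positive class = fall)\n")
  for (nm in names(v)) {
    cat(sprintf(
      "  %-11s %s\n", nm,
      if (is.na(v[nm])) "undefined (zero denominator)" else sprintf("%.2f", v[nm])
    ))
  }
  invisible(x)
}

#' Subject-wise train/test split
#'
#' Partitions a dataset manifest by subject so that no individual contributes
#' records to both sides. With the default scenario and `train_subjects =
#' 1:3` this reproduces the 60/40 split: 210 training and 140 test records
#' per radar.
#'
#' @param manifest Data frame with at least `record_id` and `subject_id`
#'   columns (see [generate_dataset()]).
#' @param train_subjects Subject ids assigned to training (default `1:3`).
#' @return Object of class `dataset_split`: `train_records`, `test_records`
#'   (record id vectors), `train_subjects`, `test_subjects`.
#' @export
split_by_subject <- function(manifest, train_subjects = 1:3) {
  stopifnot(is.data.frame(manifest), all(c("record_id", "subject_id") %in% names(manifest)))
  subjects <- sort(unique(manifest$subject_id))
  missing <- setdiff(train_subjects, subjects)
  if (length(missing)) {
    stop("train_subjects not present in manifest: ", toString(missing))
  }
  test_subjects <- setdiff(subjects, train_subjects)
  if (length(test_subjects) == 0) {
    stop("train_subjects cover all subjects: the test set would be empty")
  }
  counts <- table(factor(manifest$subject_id, levels = subjects))
  if (any(counts == 0)) {
    warning("subjects with zero records: ", toString(subjects[counts == 0]))
  }
  is_train <- manifest$subject_id %in% train_subjects
  structure(
    list(
      train_records = manifest$record_id[is_train],
      test_records = manifest$record_id[!is_train],
      train_subjects = sort(unique(manifest$subject_id[is_train])),
      test_subjects = test_subjects
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> train: %d records (subjects %s); test: %d records (subjects %s)\n",
    length(x$train_records), toString(x$train_subjects),
    length(x$test_records), toString(x$test_subjects)
  ))
  invisible(x)
}
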