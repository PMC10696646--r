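# Multi-class evaluation: confusion matrix and the four reported figures
# (accuracy, precision, sensitivity, specificity) computed one-vs-rest per
# class and averaged.

#' Build a confusion matrix over the beat vocabulary
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   grouped symbols.
#' @param labels Ordered vocabulary (default [class_labels()]).
#' @return A `beat_confusion` object: an integer matrix with rows = true
#'   class, columns = predicted class.
#' @export
confusion <- function(true_labels, predicted_labels, labels = class_labels()) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), labels)
  if (length(bad) > 0)
    stop("labels outside the vocabulary: ", paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = labels)
  pf <- factor(predicted_labels, levels = labels)
  m <- table(true = tf, predicted = pf)
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  structure(m, class = c("beat_confusion", "matrix"))
}

#' @export
print.beat_confusion <- function(x, ...) {
  cat(sprintf("<beat_confusion> %d samples\n", sum(x)))
  keep <- rowSums(x) > 0 | colSums(x) > 0
  print(unclass(x)[keep, keep, drop = FALSE])
  invisible(x)
}

#' Accuracy, precision, sensitivity and specificity from a confusion matrix
#'
#' Accuracy is `trace / total`. The other three are computed one-vs-rest per
#' class (precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`) and averaged. With `average = "macro"` the per-class values
#' are averaged over classes present in the true labels, skipping classes
#' whose denominator is zero; with `"micro"` the TP/FP/FN/TN counts are
#' pooled before forming each ratio.
#'
#' @param cm A [confusion()] matrix.
#' @param average `"macro"` (default) or `"micro"`.
#' @return List with `accuracy`, `precision`, `sensitivity`, `specificity`,
#'   and `per_class` (data frame of the one-vs-rest values).
#' @export
summarize_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  per_class <- data.frame(
    label = rownames(m),
    support = rowSums(m),
    precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp))
  rownames(per_class) <- NULL
  present <- per_class$support > 0
  avg <- function(v, keep) mean(v[keep & !is.na(v)])
  if (average == "macro") {
    precision <- avg(per_class$precision, present)
    sensitivity <- avg(per_class$sensitivity, present)
    specificity <- avg(per_class$specificity, present)
  } else {
    precision <- sum(tp[present]) / sum((tp + fp)[present])
    sensitivity <- sum(tp[present]) / sum((tp + fn)[present])
    specificity <- sum(tn[present]) / sum((tn + fp)[present])
  }
  list(accuracy = sum(tp) / total, precision = precision,
       sensitivity = sensitivity, specificity = specificity,
       average = average, per_class = per_class)
}

#' Write a metrics report as JSON and a readable table
#'
#' Rows are the four metrics; columns are the supplied settings (for example
#' epoch counts), mirroring the usual metric-by-epoch presentation.
#'
#' @param results Named list of [summarize_metrics()] outputs, one per
#'   column.
#' @param json_path,txt_path Output paths (either may be `NULL` to skip).
#' @return The table as a data frame, invisibly.
#' @export
write_metrics_report <- function(results, json_path = NULL, txt_path = NULL) {
  metric_names <- c("accuracy", "precision", "sensitivity", "specificity")
  tab <- data.frame(metric = metric_names)
  for (nm in names(results))
    tab[[nm]] <- vapply(metric_names, function(m)
      round(results[[nm]][[m]], 4), numeric(1))
  if (!is.null(json_path)) {
    payload <- lapply(results, function(r) r[metric_names])
    jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    write.table(format(tab, digits = 4), con, row.names = FALSE,
                quote = FALSE, sep = "\t")
    close(con)
  }
  invisible(tab)
}
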