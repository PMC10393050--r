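# Classification evaluation: confusion matrix, accuracy, per-class
# precision/recall/F1 and their unweighted (macro) average. The per-class F1
# is the harmonic mean 2PR/(P+R); any metric whose denominator is zero (an
# empty class) is reported as 0.

#' Evaluate a classifier against reference labels
#'
#' @param true_labels,predicted_labels Equal-length vectors; every value
#'   must appear in `class_order`.
#' @param class_order Vector fixing the class ordering of the confusion
#'   matrix rows/columns (rows = true class).
#' @return A `classifier_report`: list with `confusion` (K x K count
#'   matrix), `accuracy`, `per_class` (data frame class / precision /
#'   recall / f1 / support) and `macro_f1`. Zero-denominator metrics are 0
#'   by convention (recorded in `zero_division`).
#' @export
evaluate_classifier <- function(true_labels, predicted_labels, class_order) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_invalid("label vectors must have equal lengths")
  }
  if (length(true_labels) == 0) stop_invalid("no samples to evaluate")
  class_order <- as.character(class_order)
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  if (!all(tl %in% class_order) || !all(pl %in% class_order)) {
    stop_invalid("labels must be a subset of `class_order`")
  }
  tf <- factor(tl, levels = class_order)
  pf <- factor(pl, levels = class_order)
  confusion <- table(true = tf, predicted = pf)
  confusion <- matrix(as.integer(confusion), nrow = length(class_order),
                      dimnames = list(true = class_order,
                                      predicted = class_order))
  total <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  structure(list(
    confusion = confusion,
    accuracy = sum(tp) / total,
    per_class = data.frame(class = class_order, precision = precision,
                           recall = recall, f1 = f1,
                           support = rowSums(confusion),
                           row.names = NULL),
    macro_f1 = mean(f1),
    zero_division = "0"
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: accuracy %.4f, macro-F1 %.4f over %d classes (%d samples)\n",
              x$accuracy, x$macro_f1, nrow(x$confusion), sum(x$confusion)))
  invisible(x)
}

#' Write a classifier report to JSON and CSV
#'
#' JSON carries the confusion matrix and aggregate metrics; the per-class
#' table goes to a sidecar CSV `<stem>_per_class.csv`.
#'
#' @param report A `classifier_report`.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the JSON (e.g. run
#'   metadata).
#' @return `path`, invisibly.
#' @export
write_classifier_report <- function(report, path, extra = list()) {
  stopifnot(inherits(report, "classifier_report"))
  payload <- c(list(
    accuracy = report$accuracy,
    macro_f1 = report$macro_f1,
    zero_division = report$zero_division,
    classes = rownames(report$confusion),
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE))
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_class,
                   sub("\\.json$", "_per_class.csv", path),
                   row.names = FALSE)
  invisible(path)
}
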