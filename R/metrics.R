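#' Confusion matrix with fixed class ordering
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param true_labels,predicted_labels equal-length character vectors.
#' @param class_order the class ordering (default normal, benign,
#'   malignant).
#' @return square integer matrix with dimnames `true` x `predicted`.
#' @export
confusion <- function(true_labels, predicted_labels, class_order = CLASS_ORDER) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stopf("true and predicted label vectors differ in length (%d vs %d)",
          length(true_labels), length(predicted_labels))
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(bad)) stopf("unknown label '%s'", bad[1])
  tt <- table(factor(true_labels, levels = class_order),
              factor(predicted_labels, levels = class_order))
  m <- matrix(as.integer(tt), length(class_order), length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  m
}

#' One-vs-rest per-class metrics
#'
#' Collapses the multiclass confusion matrix around `target_class`:
#' TP = diagonal cell, FN = rest of the row, FP = rest of the column,
#' TN = everything else. Then, as percentages, sensitivity = 100 TP/(TP+FN),
#' specificity = 100 TN/(TN+FP), FPR = 100 FP/(FP+TN) (so FPR + specificity
#' = 100 identically), accuracy = 100 (TP+TN)/total. A zero denominator
#' yields `NaN` rather than an error.
#'
#' @param matrix confusion matrix from [confusion()].
#' @param target_class the class to collapse around.
#' @return `class_metrics`: list with the counts and percentage metrics.
#' @export
per_class_metrics <- function(matrix, target_class) {
  cls <- rownames(matrix)
  if (!(target_class %in% cls)) {
    stopf("class '%s' not in matrix order (%s)", target_class, paste(cls, collapse = ", "))
  }
  total <- sum(matrix)
  if (total == 0) stopf("empty confusion matrix")
  k <- match(target_class, cls)
  TP <- matrix[k, k]
  FN <- sum(matrix[k, ]) - TP
  FP <- sum(matrix[, k]) - TP
  TN <- total - TP - FN - FP
  pct <- function(num, den) if (den == 0) NaN else 100 * num / den
  structure(list(class = target_class, TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = pct(TP, TP + FN),
                 specificity = pct(TN, TN + FP),
                 fpr = pct(FP, FP + TN),
                 accuracy = pct(TP + TN, total)),
            class = "class_metrics")
}

#' Macro average of three per-class percentages
#'
#' Unweighted arithmetic mean, rounded half-up to two decimals (the
#' rendering convention of the combined results table).
#'
#' @param values numeric vector of exactly three per-class values.
#' @return the rounded mean.
#' @export
macro_average <- function(values) {
  if (length(values) != 3L) stopf("macro_average expects exactly 3 per-class values, got %d", length(values))
  round_half_up(mean(values), 2)
}

#' Build the two-technique evaluation report
#'
#' Computes per-class one-vs-rest metrics for the baseline SVM and the
#' swarm-tuned CS-SVM from pooled cross-validated predictions, plus macro
#' averages, in the standard table layout
#' `technique,dataset,fpr,specificity,sensitivity,accuracy,time_s` with one
#' `average` row per technique. Recognition times are carried through for
#' logging but never asserted (hardware-dependent).
#'
#' @param true_labels character vector of truth.
#' @param predictions named list of prediction vectors, e.g.
#'   `list(SVM = ..., `CS-SVM` = ...)`.
#' @param class_order class ordering.
#' @param times optional named numeric vector of per-technique wall-clock
#'   seconds.
#' @return `eval_report`: list with `table` (data frame, full precision),
#'   `confusions`, `overall_accuracy` (named, percent).
#' @export
eval_report <- function(true_labels, predictions, class_order = CLASS_ORDER,
                        times = NULL) {
  if (!length(predictions) || is.null(names(predictions))) {
    stopf("predictions must be a non-empty named list of prediction vectors")
  }
  rows <- list()
  confusions <- list()
  overall <- numeric(0)
  for (tech in names(predictions)) {
    pred <- predictions[[tech]]
    if (length(pred) != length(true_labels)) {
      stopf("technique '%s' has %d predictions for %d samples", tech,
            length(pred), length(true_labels))
    }
    cm <- confusion(true_labels, pred, class_order)
    confusions[[tech]] <- cm
    t_s <- if (!is.null(times) && tech %in% names(times)) times[[tech]] else NA_real_
    pc <- lapply(class_order, function(cl) per_class_metrics(cm, cl))
    for (m in pc) {
      rows[[length(rows) + 1L]] <- data.frame(
        technique = tech, dataset = m$class, fpr = m$fpr,
        specificity = m$specificity, sensitivity = m$sensitivity,
        accuracy = m$accuracy, time_s = t_s, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      technique = tech, dataset = "average",
      fpr = macro_average(vapply(pc, `[[`, 0, "fpr")),
      specificity = macro_average(vapply(pc, `[[`, 0, "specificity")),
      sensitivity = macro_average(vapply(pc, `[[`, 0, "sensitivity")),
      accuracy = macro_average(vapply(pc, `[[`, 0, "accuracy")),
      time_s = t_s, stringsAsFactors = FALSE)
    overall[tech] <- 100 * mean(pred == true_labels)
  }
  structure(list(table = do.call(rbind, rows), confusions = confusions,
                 overall_accuracy = overall, class_order = class_order),
            class = "eval_report")
}

#' Render / reload an evaluation report as CSV
#'
#' Numbers are rounded half-up to two decimals at render time only;
#' internal report values keep full precision. `read_report(render_report(x))`
#' reproduces the rendered table exactly.
#'
#' @param report an [eval_report()].
#' @param path CSV output path.
#' @return `render_report`: the rendered data frame, invisibly written to
#'   `path` when given. `read_report`: the data frame.
#' @export
render_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  tab <- report$table
  if (is.null(tab) || !nrow(tab)) stopf("report has no rows to render")
  need <- unlist(lapply(names(report$confusions), function(t)
    paste(t, c(report$class_order, "average"))))
  have <- paste(tab$technique, tab$dataset)
  if (!setequal(need, have)) {
    stopf("incomplete report: missing section(s) %s",
          paste(setdiff(need, have), collapse = ", "))
  }
  for (col in c("fpr", "specificity", "sensitivity", "accuracy", "time_s")) {
    tab[[col]] <- round_half_up(tab[[col]], 2)
  }
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @rdname render_report
#' @export
read_report <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("technique", "dataset", "fpr", "specificity", "sensitivity",
            "accuracy", "time_s")
  if (!all(need %in% names(tab))) {
    stopf("report file %s must have columns: %s", path, paste(need, collapse = ","))
  }
  tab
}
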