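#' Published per-class reference results
#'
#' The per-class results (FPR, specificity, sensitivity, recognition
#' accuracy in percent, recognition time in seconds) reported for the
#' baseline SVM and the chameleon-swarm-tuned CS-SVM on the clinical
#' malignant / benign / normal CT datasets in the original study of this
#' method. Shipped so the combined-table macro averages can be recomputed
#' with [macro_average()] and compared against the published combined
#' table. Note two published average cells (the SVM FPR average and the
#' CS-SVM time average) are arithmetically inconsistent with these
#' per-class inputs; [macro_average()] reproduces only the consistent
#' cells.
#'
#' @return data frame with columns `technique`, `dataset`, `fpr`,
#'   `specificity`, `sensitivity`, `accuracy`, `time_s`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv", package = "cssvm",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
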