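#' Published validation confusion matrix (AHI vs RE HRAI)
#'
#' The five-class agreement table between polysomnographic AHI severity
#' classes and respiratory-related heart-rate-acceleration index (RE
#' HRAI) classes reported for a 653-study community validation sample,
#' bundled as example data. Bins are half-open at the conventional
#' severity cuts 5, 10, 15 and 30 events/h. Collapsing this table at a
#' predictor cut of 5 events/h and AHI cuts of 5/10/15/30 reproduces the
#' published diagnostic performance of the pulse-rate index.
#'
#' @return A `confusion_matrix` (see [confusion_from_counts()]) with
#'   `bin_edges = c(5, 10, 15, 30)` and n = 653.
#' @examples
#' cm <- validation_confusion()
#' diagnostic_stats(collapse_confusion(cm, 10, 5))
#' @export
validation_confusion <- function() {
  path <- system.file("extdata", "ahi_rehrai_validation_confusion.csv",
                      package = "rrdip", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  dimnames(m) <- NULL
  confusion_from_counts(m, bin_edges = c(5, 10, 15, 30))
}
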