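#' Example seven-pattern confusion table
#'
#' A reference confusion table for classifying seven gait patterns (walk
#' forward/left/right, upstairs, downstairs, run, sit) from hip-worn
#' accelerometer windows, with 140 test windows per true class. Rows are
#' true classes, columns predicted classes. Shipped as a worked example for
#' [multiclass_metrics()]: its overall accuracy rounds to 92% and the `sit`
#' class attains 99% precision and recall.
#'
#' @return A 7 x 7 integer matrix with class dimnames.
#' @examples
#' m <- multiclass_metrics(example_confusion_table())
#' round_half_up(m$overall_accuracy)
#' @export
example_confusion_table <- function() {
  path <- system.file("extdata", "seven_gait_confusion.csv",
                      package = "gaitcs", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
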