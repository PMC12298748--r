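#' Bundled reference confusion matrices
#'
#' Published epoch-count confusion matrices of the reference classifier on
#' the Sleep-EDF benchmark (the 20-subject 2013 subset and the 78-subject
#' 2018 expansion), used to validate the metrics stack against known
#' overall and per-class values.
#'
#' @param which `"sleepedf20"` or `"sleepedf78"`.
#' @return Integer matrix `[5 x 5]`, rows = ground truth.
#' @export
reference_confusion <- function(which = c("sleepedf20", "sleepedf78")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("confusion_", which, ".csv"),
                      package = "mcafnet", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(df)
  dimnames(m) <- list(truth = stage_levels(), pred = stage_levels())
  storage.mode(m) <- "integer"
  m
}
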