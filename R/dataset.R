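#' Save or load a dataset / tensor container
#'
#' Datasets (raw epochs or preprocessed tensor stacks) are stored as native
#' serialized R containers; writing is deterministic, so identical inputs
#' produce byte-identical files.
#'
#' @param x A `psg_dataset` or the list returned by [preprocess_epochs()].
#' @param path Destination / source file path (conventionally `.rds`).
#' @return `write_container()` returns `path` invisibly; `read_container()`
#'   the stored object.
#' @export
write_container <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  readRDS(path)
}

# labels/subjects/tensor views used by training code
dataset_tensors <- function(prep, subjects = NULL) {
  sel <- if (is.null(subjects)) seq_len(dim(prep$tf)[1]) else
    which(prep$subjects %in% subjects)
  list(x = prep$tf[sel, , , , drop = FALSE],
       y = prep$labels[sel],
       subjects = prep$subjects[sel])
}
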