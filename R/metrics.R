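#' Build a 5x5 sleep-stage confusion matrix
#'
#' Rows are ground truth, columns are predictions, both in the canonical
#' order W, N1, N2, N3, REM.
#'
#' @param truth,pred Stage sequences (character or factor) of equal length.
#' @return Integer matrix `[5 x 5]` with dimnames.
#' @export
build_confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  t_f <- as_stage_factor(truth)
  p_f <- as_stage_factor(pred)
  if (anyNA(t_f) || anyNA(p_f)) abort("stage sequences contain missing labels")
  m <- table(truth = t_f, pred = p_f)
  matrix(as.integer(m), 5, 5, dimnames = list(truth = stage_levels(),
                                              pred = stage_levels()))
}

#' Derive all reported metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 (one-vs-rest), overall accuracy,
#' Cohen's kappa, macro-F1 (unweighted mean of the five F1 scores),
#' macro-averaged sensitivity (mean recall) and macro-averaged specificity
#' (mean one-vs-rest TN / (TN + FP)). Empty rows or columns yield 0 under
#' the 0/0 -> 0 convention and are flagged.
#'
#' @param confusion Nonnegative count matrix `[5 x 5]`, rows = truth.
#' @return An object of class `stage_metrics`.
#' @export
metrics_from_confusion <- function(confusion) {
  cm <- as.matrix(confusion)
  if (!all(dim(cm) == c(5, 5))) abort("expected a 5 x 5 confusion matrix")
  if (any(cm < 0)) abort("confusion counts must be nonnegative")
  total <- sum(cm)
  if (total == 0) abort("confusion matrix is empty")
  rs <- rowSums(cm)
  cs <- colSums(cm)
  dg <- diag(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(dg, cs)
  recall <- safe_div(dg, rs)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- sum(dg) / total
  p_e <- sum(rs * cs) / total^2
  kappa <- if (p_e == 1) 1 else (accuracy - p_e) / (1 - p_e)
  specificity <- vapply(seq_len(5), function(k) {
    tn <- sum(cm[-k, -k])
    fp <- sum(cm[-k, k])
    if (tn + fp == 0) 0 else tn / (tn + fp)
  }, numeric(1))
  degenerate <- stage_levels()[rs == 0 | cs == 0]
  structure(
    list(confusion = cm,
         per_class = tibble::tibble(
           stage = factor(stage_levels(), levels = stage_levels()),
           precision = unname(precision), recall = unname(recall),
           f1 = unname(f1), specificity = unname(specificity),
           support = unname(as.integer(rs))),
         accuracy = accuracy,
         kappa = kappa,
         macro_f1 = mean(f1),
         sensitivity = mean(recall),
         specificity = mean(specificity),
         degenerate_classes = degenerate,
         n = total),
    class = "stage_metrics")
}

#' @export
print.stage_metrics <- function(x, ...) {
  cat(sprintf("<stage_metrics> n=%d  accuracy %.1f%%  kappa %.2f  macro-F1 %.1f%%\n",
              x$n, 100 * x$accuracy, x$kappa, 100 * x$macro_f1))
  print(x$per_class)
  if (length(x$degenerate_classes) > 0) {
    cat("note: degenerate (empty) classes:",
        paste(x$degenerate_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname metrics_from_confusion
#' @param x A `stage_metrics` object.
#' @param ... Unused.
#' @export
tidy.stage_metrics <- function(x, ...) x$per_class

#' @rdname metrics_from_confusion
#' @export
glance.stage_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, kappa = x$kappa, macro_f1 = x$macro_f1,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n = x$n)
}

#' Compare predictions with truth in one call
#'
#' Convenience wrapper: [build_confusion()] then [metrics_from_confusion()].
#'
#' @inheritParams build_confusion
#' @return A `stage_metrics` object.
#' @export
score_predictions <- function(truth, pred) {
  metrics_from_confusion(build_confusion(truth, pred))
}

#' Hypnogram as a tidy data frame
#'
#' @param truth,pred Aligned stage sequences.
#' @param epoch_seconds Epoch duration (30 s by convention).
#' @return Tibble with `time_s`, `truth`, `pred`.
#' @export
hypnogram_frame <- function(truth, pred, epoch_seconds = 30) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  tibble::tibble(time_s = (seq_along(truth) - 1) * epoch_seconds,
                 truth = as_stage_factor(truth),
                 pred = as_stage_factor(pred))
}

#' Plot a two-panel hypnogram
#'
#' Step plot of stage versus time for the ground truth (upper panel) and the
#' predictions (lower panel), with the conventional depth ordering on the
#' y-axis (W on top, N3 at the bottom, REM between W and N1).
#'
#' @inheritParams hypnogram_frame
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(truth, pred, epoch_seconds = 30) {
  df <- hypnogram_frame(truth, pred, epoch_seconds)
  y_order <- c("N3", "N2", "N1", "REM", "W")
  long <- tidyr::pivot_longer(df, c("truth", "pred"),
                              names_to = "panel", values_to = "stage")
  long$panel <- factor(long$panel, levels = c("truth", "pred"),
                       labels = c("ground truth", "predicted"))
  long$stage_y <- as.integer(factor(as.character(long$stage), levels = y_order))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 3600, y = .data$stage_y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = seq_along(y_order), labels = y_order) +
    ggplot2::labs(x = "time (h)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Render a hypnogram to image and CSV files
#'
#' @inheritParams hypnogram_frame
#' @param image_path Output image path (extension selects the device, e.g.
#'   `.png` or `.svg`).
#' @param csv_path Output CSV of `(time_s, truth, pred)`.
#' @param width,height Image size in inches.
#' @return Invisibly, the tidy hypnogram tibble.
#' @export
render_hypnogram <- function(truth, pred, image_path, csv_path,
                             epoch_seconds = 30, width = 8, height = 4) {
  df <- hypnogram_frame(truth, pred, epoch_seconds)
  p <- plot_hypnogram(truth, pred, epoch_seconds)
  ggplot2::ggsave(image_path, p, width = width, height = height)
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}

#' Aggregate attention maps per predicted stage
#'
#' Averages the cross-channel attention weights over heads, both temporal
#' axes, and all epochs predicted as each stage, yielding one C x C matrix
#' per stage (rows = query channel, columns = key channel). Stages with no
#' epochs yield all-NaN matrices and are flagged.
#'
#' @param maps Attention array `[B x H x C x C x L x L]` for one fusion
#'   layer (from `model_forward(..., keep_attention = TRUE)`), or a list of
#'   such arrays (stacked along B after aggregation of each).
#' @param stages Predicted stage per epoch (length B, or total B over the
#'   list).
#' @param channel_names Optional channel labels for the output.
#' @return List with `matrices` (named list of C x C matrices per stage),
#'   `tidy` (tibble stage/query/key/weight), `empty_stages`.
#' @export
aggregate_attention <- function(maps, stages,
                                channel_names = NULL) {
  if (is.list(maps)) maps <- do.call(abind4_first, maps)
  d <- dim(maps)
  if (length(d) != 6) abort("expected an attention array [B x H x C x C x L x L]")
  stages <- as_stage_factor(stages)
  if (length(stages) != d[1]) abort("stage vector length does not match maps")
  c_n <- d[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(c_n))
  # per-epoch aggregate: mean over heads and both time axes -> [B x C x C]
  per_epoch <- array(0, dim = c(d[1], c_n, c_n))
  for (i in seq_len(c_n)) for (j in seq_len(c_n)) {
    block <- maps[, , i, j, , , drop = FALSE]
    dim(block) <- c(d[1], d[2] * d[5] * d[6])
    per_epoch[, i, j] <- rowMeans(block)
  }
  mats <- list()
  empty <- character(0)
  rows <- list()
  for (s in stage_levels()) {
    sel <- which(stages == s)
    m <- if (length(sel) == 0) {
      empty <- c(empty, s)
      matrix(NaN, c_n, c_n)
    } else {
      apply(per_epoch[sel, , , drop = FALSE], c(2, 3), mean)
    }
    dimnames(m) <- list(query = channel_names, key = channel_names)
    mats[[s]] <- m
    rows[[s]] <- tibble::tibble(
      stage = s,
      query = rep(channel_names, times = c_n),
      key = rep(channel_names, each = c_n),
      weight = as.numeric(m))
  }
  list(matrices = mats,
       tidy = dplyr::bind_rows(rows),
       empty_stages = empty)
}

# stack 6-d arrays along the first axis
abind4_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(n, d[-1]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , , , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
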