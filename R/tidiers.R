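#' Tidy a training run
#'
#' @param x An `mcaf_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-pass history tibble (pass, train_loss, train_acc,
#'   val_loss, val_acc).
#' @export
tidy.mcaf_fit <- function(x, ...) x$history

#' @rdname tidy.mcaf_fit
#' @export
glance.mcaf_fit <- function(x, ...) {
  tibble::tibble(passes = nrow(x$history),
                 best_pass = x$best_pass,
                 best_val_acc = max(x$history$val_acc),
                 final_train_acc = x$history$train_acc[nrow(x$history)],
                 learning_rate = x$config$learning_rate,
                 batch_size = x$config$batch_size)
}

#' Training curves
#'
#' Loss and accuracy per pass for the training and validation sets, with
#' the selected (best-validation) pass marked.
#'
#' @param object An `mcaf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcaf_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(pass = h$pass, value = h$train_loss, set = "train", metric = "loss"),
    tibble::tibble(pass = h$pass, value = h$val_loss, set = "validation", metric = "loss"),
    tibble::tibble(pass = h$pass, value = h$train_acc, set = "train", metric = "accuracy"),
    tibble::tibble(pass = h$pass, value = h$val_acc, set = "validation", metric = "accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pass, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_pass, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training pass", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a model's parameter inventory
#'
#' @param x An `mcaf_model`.
#' @param ... Unused.
#' @return Tibble of parameter counts per submodule.
#' @export
tidy.mcaf_model <- function(x, ...) count_parameters(x)$by_module

#' @rdname tidy.mcaf_model
#' @export
glance.mcaf_model <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(d = cfg$d, channels = cfg$c_channels, frames = cfg$l_frames,
                 heads = cfg$heads, fusion_layers = cfg$n_attention_layers,
                 hidden = cfg$hidden, classes = cfg$n_classes,
                 parameters = count_parameters(x)$total)
}

#' Heatmap of aggregated cross-channel attention
#'
#' @param attention Result of [aggregate_attention()].
#' @return A ggplot object, one C x C panel per stage.
#' @export
plot_attention <- function(attention) {
  df <- attention$tidy
  df$stage <- factor(df$stage, levels = stage_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~stage, nrow = 1) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "key channel", y = "query channel",
                  fill = "attention") +
    ggplot2::theme_minimal()
}
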