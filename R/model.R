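#' Model architecture configuration
#'
#' All architecture hyperparameters of the classifier. Defaults give the
#' full-size network: 128 spectrogram features, 3 channels, 29 time frames,
#' 4 attention heads, 2 fusion layers, a 512-unit hidden layer and 5 output
#' classes.
#'
#' @param d Feature dimension D (spectrogram frequency bins).
#' @param c_channels Number of signal channels C.
#' @param l_frames Time frames per epoch L.
#' @param heads Attention heads H; must divide `d`.
#' @param n_attention_layers Number of fusion layers.
#' @param hidden Hidden units of the classifier head.
#' @param n_classes Output classes (5 sleep stages).
#' @param dropout Dropout rate applied after the hidden ReLU layer.
#' @param kernel Temporal convolution kernel length (odd).
#' @param expansion Widening factor of the temporal convolution.
#' @param temporal_pool Reduction over the time axis before the classifier:
#'   `"mean"` (default), `"last"` or `"max"`.
#' @param use_temporal_conv Include the per-channel temporal convolution
#'   stage (disable for the ablation without it).
#' @param use_fusion Include the cross-channel attention fusion stack
#'   (disable for the naive concatenation ablation).
#' @param dense_conv Use a dense instead of depthwise-separable widening
#'   convolution.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d = 128, c_channels = 3, l_frames = 29, heads = 4,
                         n_attention_layers = 2, hidden = 512, n_classes = 5,
                         dropout = 0.5, kernel = 3, expansion = 2,
                         temporal_pool = c("mean", "last", "max"),
                         use_temporal_conv = TRUE, use_fusion = TRUE,
                         dense_conv = FALSE) {
  temporal_pool <- match.arg(temporal_pool)
  if (d %% heads != 0) abort("d must be divisible by heads")
  if (kernel %% 2 != 1) abort("kernel must be odd")
  structure(
    list(d = as.integer(d), c_channels = as.integer(c_channels),
         l_frames = as.integer(l_frames), heads = as.integer(heads),
         n_attention_layers = as.integer(n_attention_layers),
         hidden = as.integer(hidden), n_classes = as.integer(n_classes),
         dropout = dropout, kernel = as.integer(kernel),
         expansion = as.integer(expansion), temporal_pool = temporal_pool,
         use_temporal_conv = use_temporal_conv, use_fusion = use_fusion,
         dense_conv = dense_conv),
    class = "model_config"
  )
}

#' Build a model with freshly initialized parameters
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `mcaf_model` holding the config and a nested
#'   parameter list (`tconv`, `fusion`, `head`).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  params <- list()
  if (cfg$use_temporal_conv) {
    params$tconv <- lapply(seq_len(cfg$c_channels), function(i) {
      temporal_conv_init(cfg$d, cfg$kernel, cfg$expansion, cfg$dense_conv)
    })
  }
  if (cfg$use_fusion) {
    params$fusion <- lapply(seq_len(cfg$n_attention_layers), function(i) {
      attention_init(cfg$d, cfg$heads)
    })
  }
  cd <- cfg$c_channels * cfg$d
  lim1 <- sqrt(6 / cd)
  lim2 <- sqrt(6 / cfg$hidden)
  params$head <- list(
    w1 = matrix(runif(cd * cfg$hidden, -lim1, lim1), cd, cfg$hidden),
    b1 = numeric(cfg$hidden),
    w2 = matrix(runif(cfg$hidden * cfg$n_classes, -lim2, lim2),
                cfg$hidden, cfg$n_classes),
    b2 = numeric(cfg$n_classes)
  )
  structure(list(config = cfg, params = params), class = "mcaf_model")
}

#' @export
print.mcaf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mcaf_model> D=%d C=%d L=%d H=%d layers=%d hidden=%d classes=%d (%s params)\n",
              cfg$d, cfg$c_channels, cfg$l_frames, cfg$heads,
              cfg$n_attention_layers, cfg$hidden, cfg$n_classes,
              format(count_parameters(x)$total, big.mark = ",")))
  invisible(x)
}

pool_time <- function(y, rule) {
  d <- dim(y)
  switch(rule,
    mean = {
      p <- array(y, dim = c(d[1] * d[2], d[3], d[4]))
      p <- aperm(p, c(2, 1, 3))
      dim(p) <- c(d[3], d[1] * d[2] * d[4])
      list(p = array(colMeans(p), dim = c(d[1], d[2], d[4])), amax = NULL)
    },
    last = list(p = array(y[, , d[3], ], dim = c(d[1], d[2], d[4])), amax = NULL),
    max = {
      p <- apply(y, c(1, 2, 4), max)
      amax <- apply(y, c(1, 2, 4), which.max)
      list(p = p, amax = amax)
    })
}

#' Forward pass of the classifier
#'
#' Pipeline: per-channel temporal convolution, fusion stack, temporal
#' pooling, flatten to `C*D`, hidden affine + ReLU + dropout, output affine,
#' softmax.
#'
#' @param model An `mcaf_model`.
#' @param x Array `[B x C x L x D]` of standardized spectrogram tensors.
#' @param training If `TRUE`, dropout is active and a backprop cache is
#'   returned.
#' @param keep_attention If `TRUE`, return per-layer attention weight arrays.
#' @return List with `probs` `[B x n_classes]`, `logits`, and optionally
#'   `attention` (list per fusion layer), `gates`, `cache`.
#' @export
model_forward <- function(model, x, training = FALSE, keep_attention = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 4 || d[2] != cfg$c_channels || d[4] != cfg$d) {
    abort(sprintf("input shape [%s] does not match config (C=%d, D=%d)",
                  paste(d, collapse = " x "), cfg$c_channels, cfg$d))
  }
  cache <- list()
  h_in <- x
  # per-channel temporal features
  tcaches <- NULL
  if (cfg$use_temporal_conv) {
    out <- array(0, dim = d)
    tcaches <- vector("list", cfg$c_channels)
    for (c_i in seq_len(cfg$c_channels)) {
      m <- channel_stack(h_in, c_i)
      res <- temporal_conv_channel_forward(m, model$params$tconv[[c_i]],
                                           d[3], d[1], cfg$kernel,
                                           cfg$expansion, cfg$dense_conv)
      out[, c_i, , ] <- channel_unstack(res$y, d[1], d[3], d[4])
      if (training) tcaches[[c_i]] <- res$cache
    }
    h_in <- out
  }
  # fusion stack
  fcaches <- NULL
  attention <- if (keep_attention) vector("list", cfg$n_attention_layers) else NULL
  gates <- NULL
  if (cfg$use_fusion) {
    fcaches <- vector("list", cfg$n_attention_layers)
    gates <- matrix(0, cfg$n_attention_layers, d[1])
    for (i in seq_len(cfg$n_attention_layers)) {
      res <- fuse_layer(h_in, model$params$fusion[[i]],
                        keep_weights = keep_attention, training = training)
      h_in <- res$y
      gates[i, ] <- res$gate
      if (training) fcaches[[i]] <- res$cache
      if (keep_attention) attention[[i]] <- res$weights
    }
  }
  # pool, flatten, classify
  pooled <- pool_time(h_in, cfg$temporal_pool)
  pmat <- pooled$p
  dim(pmat) <- c(d[1], cfg$c_channels * cfg$d)
  z1 <- pmat %*% model$params$head$w1 + rep(model$params$head$b1, each = d[1])
  r1 <- relu(z1)
  if (training && cfg$dropout > 0) {
    mask <- matrix(runif(length(r1)) >= cfg$dropout, nrow(r1), ncol(r1))
    r1d <- r1 * mask / (1 - cfg$dropout)
  } else {
    mask <- NULL
    r1d <- r1
  }
  logits <- r1d %*% model$params$head$w2 + rep(model$params$head$b2, each = d[1])
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, gates = gates)
  if (keep_attention) out$attention <- attention
  if (training) {
    out$cache <- list(dims = d, tcaches = tcaches, fcaches = fcaches,
                      pmat = pmat, z1 = z1, mask = mask, r1d = r1d,
                      pool_amax = pooled$amax)
  }
  out
}

# cross-entropy loss (mean over the batch) from probabilities
cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-300)))
}

# backward pass; y_idx is the integer class index per sample.
# Returns gradients in the same nested structure as model$params.
model_backward <- function(model, fwd, y_idx) {
  cfg <- model$config
  cache <- fwd$cache
  d <- cache$dims
  b <- d[1]
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(b), y_idx)] <- dlogits[cbind(seq_len(b), y_idx)] - 1
  dlogits <- dlogits / b
  grads <- list()
  grads$head <- list(
    w1 = NULL, b1 = NULL,
    w2 = t(cache$r1d) %*% dlogits,
    b2 = colSums(dlogits)
  )
  dr1d <- dlogits %*% t(model$params$head$w2)
  dr1 <- if (!is.null(cache$mask)) dr1d * cache$mask / (1 - cfg$dropout) else dr1d
  dz1 <- dr1 * (cache$z1 > 0)
  grads$head$w1 <- t(cache$pmat) %*% dz1
  grads$head$b1 <- colSums(dz1)
  dpmat <- dz1 %*% t(model$params$head$w1)
  dp <- array(dpmat, dim = c(b, cfg$c_channels, cfg$d))
  # un-pool over time
  dy <- array(0, dim = d)
  if (cfg$temporal_pool == "mean") {
    for (l in seq_len(d[3])) dy[, , l, ] <- dp / d[3]
  } else if (cfg$temporal_pool == "last") {
    dy[, , d[3], ] <- dp
  } else {
    for (bi in seq_len(b)) for (ci in seq_len(cfg$c_channels)) {
      idx <- cache$pool_amax[bi, ci, ]
      dy[cbind(bi, ci, idx, seq_len(cfg$d))] <- dp[bi, ci, ]
    }
  }
  # fusion stack backward (reverse order)
  if (cfg$use_fusion) {
    grads$fusion <- vector("list", cfg$n_attention_layers)
    for (i in rev(seq_len(cfg$n_attention_layers))) {
      res <- fuse_layer_backward(dy, model$params$fusion[[i]], cache$fcaches[[i]])
      dy <- res$dx
      grads$fusion[[i]] <- res$grads
    }
  }
  # temporal conv backward
  if (cfg$use_temporal_conv) {
    grads$tconv <- vector("list", cfg$c_channels)
    for (c_i in seq_len(cfg$c_channels)) {
      m_dy <- channel_stack(dy, c_i)
      res <- temporal_conv_channel_backward(m_dy, model$params$tconv[[c_i]],
                                            cache$tcaches[[c_i]], d[3], b,
                                            cfg$kernel, cfg$expansion,
                                            cfg$dense_conv)
      grads$tconv[[c_i]] <- res$grads
    }
  }
  grads[names(model$params)]
}

#' Count trainable parameters
#'
#' @param model An `mcaf_model`.
#' @return List with `total` and a tibble `by_module` (module, parameters).
#' @export
count_parameters <- function(model) {
  skip_heads <- function(p) {
    if (is.list(p)) p$heads <- NULL
    p
  }
  counts <- purrr::imap_dbl(model$params, function(p, nm) {
    if (nm == "fusion") {
      sum(vapply(p, function(layer) params_count(skip_heads(layer)), numeric(1)))
    } else {
      params_count(p)
    }
  })
  list(total = sum(counts),
       by_module = tibble::tibble(module = names(counts),
                                  parameters = as.numeric(counts)))
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the full configuration and a format-version string;
#' round-tripping preserves every parameter bit-exactly.
#'
#' @param model An `mcaf_model`.
#' @param path Destination file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format_version = "mcafnet-checkpoint-1",
               config = model$config, params = model$params),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param expected_config Optional [model_config()]; if supplied, every field
#'   must match the checkpoint's embedded config, and the error names the
#'   first differing field.
#' @return An `mcaf_model`.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) abort(paste0("cannot parse checkpoint: ",
                                                   conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format_version, "mcafnet-checkpoint-1")) {
    abort("cannot parse checkpoint: unrecognized format")
  }
  if (!is.null(expected_config)) {
    for (f in names(expected_config)) {
      if (!identical(expected_config[[f]], obj$config[[f]])) {
        abort(sprintf("checkpoint config mismatch in field '%s': %s vs %s",
                      f, format(obj$config[[f]]), format(expected_config[[f]])))
      }
    }
  }
  structure(list(config = obj$config, params = obj$params), class = "mcaf_model")
}
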