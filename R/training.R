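#' Training protocol configuration
#'
#' Defaults are the reference protocol: AdamW with learning rate 5e-6,
#' decoupled weight decay 1e-2, betas (0.9, 0.999), epsilon 1e-2 (an
#' unusually large value, kept configurable), mini-batches of 64, and early
#' stopping once validation accuracy has not strictly improved for 20
#' consecutive passes.
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param beta1,beta2 AdamW moment decay rates.
#' @param adam_epsilon Denominator stabilizer.
#' @param batch_size Mini-batch size.
#' @param patience Passes without validation-accuracy improvement before
#'   stopping.
#' @param max_epochs Hard bound on training passes.
#' @param seed Seed for shuffling, dropout and any other training
#'   randomness.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-6, weight_decay = 1e-2,
                         beta1 = 0.9, beta2 = 0.999, adam_epsilon = 1e-2,
                         batch_size = 64, patience = 20, max_epochs = 200,
                         seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, patience >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, adam_epsilon = adam_epsilon,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  zeros <- params_map(function(p) if (is.numeric(p)) p * 0 else p, params)
  list(m = zeros, v = zeros, step = 0L)
}

# one AdamW step with decoupled weight decay:
#   p <- p - lr * wd * p - lr * mhat / (sqrt(vhat) + eps)
# tree leaves named "heads" are architecture constants and are skipped
adamw_step <- function(params, grads, state, cfg) {
  state$step <- state$step + 1L
  corr1 <- 1 - cfg$beta1^state$step
  corr2 <- 1 - cfg$beta2^state$step
  upd <- function(p, g, m, v, nm) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        nmi <- if (!is.null(names(p))) names(p)[i] else ""
        if (identical(nmi, "heads")) next
        res <- upd(p[[i]], g[[i]], m[[i]], v[[i]], nmi)
        out_p[[i]] <- res$p; out_m[[i]] <- res$m; out_v[[i]] <- res$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- cfg$beta1 * m + (1 - cfg$beta1) * g
      v2 <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
      mhat <- m2 / corr1
      vhat <- v2 / corr2
      p2 <- p - cfg$learning_rate * cfg$weight_decay * p -
        cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_epsilon)
      list(p = p2, m = m2, v = v2)
    }
  }
  res <- upd(params, grads, state$m, state$v, "")
  list(params = res$p, state = list(m = res$m, v = res$v, step = state$step))
}

# ---- subject-wise k-fold --------------------------------------------------

#' Subject-wise k-fold cross-validation plan
#'
#' Partitions subjects (never epochs) into k groups of near-equal size.
#' For fold f, the test set is group f, the validation set is the next
#' group cyclically (so it always has the same number of subjects as the
#' test set when group sizes are equal), and the remaining groups train.
#'
#' @param subject_ids Character vector (duplicates allowed; the unique set
#'   is partitioned).
#' @param k Number of folds; at most the number of unique subjects.
#' @param seed Seed making the partition deterministic.
#' @return An object of class `fold_plan`: tibble `assignments`
#'   (subject_id, fold) and list `folds` of `train`/`val`/`test` subject
#'   sets.
#' @export
split_subjects_kfold <- function(subject_ids, k, seed = 1L) {
  subjects <- sort(unique(as.character(subject_ids)))
  n <- length(subjects)
  if (k > n) abort(sprintf("k = %d exceeds the number of subjects (%d)", k, n))
  set.seed(seed)
  shuffled <- sample(subjects)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  group <- rep(seq_len(k), times = sizes)
  assignments <- tibble::tibble(subject_id = shuffled, fold = group) |>
    dplyr::arrange(.data$subject_id)
  groups <- split(shuffled, group)
  folds <- lapply(seq_len(k), function(f) {
    val_f <- f %% k + 1L
    list(test = groups[[f]],
         val = groups[[val_f]],
         train = unlist(groups[-c(f, val_f)], use.names = FALSE))
  })
  structure(list(assignments = assignments, folds = folds, k = k, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d subjects in %d folds (seed %d)\n",
              nrow(x$assignments), x$k, x$seed))
  invisible(x)
}

# ---- early stopping -------------------------------------------------------

# given the sequence of validation accuracies so far, return the pass at
# which training stops (or NA if it should continue), and the best pass.
# Improvement is strict; ties keep the earliest pass.
early_stop_status <- function(val_accuracies, patience) {
  best_pass <- which.max(val_accuracies)
  since <- length(val_accuracies) - best_pass
  list(best_pass = best_pass,
       stop = since >= patience)
}

# ---- training loop --------------------------------------------------------

#' Train a model on tensor batches
#'
#' Cross-entropy + AdamW mini-batch training with per-pass shuffling (each
#' epoch is classified independently; no inter-epoch context is used), and
#' early stopping on validation accuracy: the parameters with the best
#' validation accuracy (earliest pass on ties) are returned.
#'
#' @param model An `mcaf_model` to start from.
#' @param x Training tensors `[N x C x L x D]`.
#' @param y Training stage labels (factor or character).
#' @param x_val,y_val Validation set in the same form.
#' @param cfg A [train_config()].
#' @param verbose Print one line per pass.
#' @return An object of class `mcaf_fit`: `model` (best parameters),
#'   `history` (tibble pass/train_loss/train_acc/val_loss/val_acc),
#'   `best_pass`, `config`.
#' @export
train_model <- function(model, x, y, x_val, y_val, cfg = train_config(),
                        verbose = FALSE) {
  y_idx <- as.integer(as_stage_factor(y))
  yv_idx <- as.integer(as_stage_factor(y_val))
  n <- dim(x)[1]
  if (n < 1) abort("no training samples")
  set.seed(cfg$seed)
  state <- adamw_init(model$params)
  history <- vector("list", cfg$max_epochs)
  val_accs <- numeric(0)
  best_params <- model$params
  best_pass <- 0L
  for (pass in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0
    tot_correct <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[idx, , , , drop = FALSE]
      yb <- y_idx[idx]
      fwd <- model_forward(model, xb, training = TRUE)
      loss <- cross_entropy(fwd$probs, yb)
      if (!is.finite(loss)) {
        abort(sprintf("non-finite training loss at pass %d (batch starting %d)",
                      pass, start))
      }
      tot_loss <- tot_loss + loss * length(idx)
      tot_correct <- tot_correct + sum(max.col(fwd$probs, ties.method = "first") == yb)
      grads <- model_backward(model, fwd, yb)
      res <- adamw_step(model$params, grads, state, cfg)
      model$params <- res$params
      state <- res$state
    }
    ev <- evaluate_tensors(model, x_val, yv_idx, cfg$batch_size)
    val_accs <- c(val_accs, ev$accuracy)
    st <- early_stop_status(val_accs, cfg$patience)
    if (st$best_pass == pass) {
      best_params <- model$params
      best_pass <- pass
    }
    history[[pass]] <- tibble::tibble(
      pass = pass, train_loss = tot_loss / n, train_acc = tot_correct / n,
      val_loss = ev$loss, val_acc = ev$accuracy)
    if (verbose) {
      message(sprintf("pass %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      pass, tot_loss / n, tot_correct / n, ev$loss, ev$accuracy))
    }
    if (st$stop) break
  }
  model$params <- best_params
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 best_pass = best_pass,
                 config = cfg),
            class = "mcaf_fit")
}

#' @export
print.mcaf_fit <- function(x, ...) {
  cat(sprintf("<mcaf_fit> %d passes, best validation accuracy %.3f at pass %d\n",
              nrow(x$history), max(x$history$val_acc), x$best_pass))
  invisible(x)
}

# batched evaluation helper on integer class indices
evaluate_tensors <- function(model, x, y_idx, batch_size = 64L) {
  n <- dim(x)[1]
  loss <- 0
  correct <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- model_forward(model, x[idx, , , , drop = FALSE], training = FALSE)
    loss <- loss + cross_entropy(fwd$probs, y_idx[idx]) * length(idx)
    correct <- correct + sum(max.col(fwd$probs, ties.method = "first") == y_idx[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Predict stages for a tensor stack
#'
#' Batched deterministic (evaluation-mode) forward passes preserving input
#' order.
#'
#' @param model An `mcaf_model` (or `mcaf_fit`, whose best model is used).
#' @param x Array `[N x C x L x D]`.
#' @param batch_size Mini-batch size for the forward passes.
#' @return Tibble with `epoch_index` (1-based input position), one
#'   probability column per stage (`p_W` .. `p_REM`), and `predicted`
#'   (stage factor).
#' @export
predict_stages <- function(model, x, batch_size = 64L) {
  if (inherits(model, "mcaf_fit")) model <- model$model
  n <- if (length(dim(x)) == 4) dim(x)[1] else 0L
  lv <- stage_levels()
  if (n == 0) {
    out <- tibble::tibble(epoch_index = integer(0))
    for (s in lv) out[[paste0("p_", s)]] <- numeric(0)
    out$predicted <- factor(character(0), levels = lv)
    return(out)
  }
  probs <- matrix(0, n, length(lv))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- model_forward(model, x[idx, , , , drop = FALSE], training = FALSE)
    probs[idx, ] <- fwd$probs
  }
  out <- tibble::tibble(epoch_index = seq_len(n))
  for (i in seq_along(lv)) out[[paste0("p_", lv[i])]] <- probs[, i]
  out$predicted <- factor(lv[max.col(probs, ties.method = "first")], levels = lv)
  out
}
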