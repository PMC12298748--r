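test_that("AdamW matches a hand-coded decoupled-weight-decay update for 100 steps", {
  # quadratic loss 0.5 * (theta - c)' A (theta - c) on two parameters
  a_mat <- matrix(c(3, 0.5, 0.5, 1), 2)
  center <- c(1, -2)
  grad_fn <- function(theta) as.numeric(a_mat %*% (theta - center))
  cfg <- train_config(learning_rate = 0.01, weight_decay = 0.1,
                      beta1 = 0.9, beta2 = 0.999, adam_epsilon = 1e-2)
  theta <- c(5, 5)
  params <- list(w = theta)
  state <- mcafnet:::adamw_init(params)
  for (t in 1:100) {
    g <- list(w = grad_fn(params$w))
    res <- mcafnet:::adamw_step(params, g, state, cfg)
    params <- res$params
    state <- res$state
  }
  ref <- reference_adamw(theta, grad_fn, 100, 0.01, 0.1, 0.9, 0.999, 1e-2)
  expect_lt(max(abs(params$w - ref)), 1e-10)
  # decay is decoupled: with zero gradients parameters shrink multiplicatively
  params2 <- list(w = c(2, -3))
  state2 <- mcafnet:::adamw_init(params2)
  res2 <- mcafnet:::adamw_step(params2, list(w = c(0, 0)), state2, cfg)
  expect_equal(res2$params$w, c(2, -3) * (1 - 0.01 * 0.1), tolerance = 1e-12)
})

test_that("subject-wise k-fold splits have the stated sizes and no leakage", {
  subs20 <- sprintf("S%02d", 1:20)
  plan <- split_subjects_kfold(subs20, 20, seed = 7)
  expect_s3_class(plan$assignments, "tbl_df")
  for (f in plan$folds) {
    expect_length(f$test, 1)
    expect_length(f$val, 1)
    expect_length(f$train, 18)
  }
  subs78 <- sprintf("P%02d", 1:78)
  plan78 <- split_subjects_kfold(subs78, 10, seed = 7)
  sizes <- sort(table(plan78$assignments$fold))
  expect_equal(unname(as.integer(sizes)), c(7, 7, 8, 8, 8, 8, 8, 8, 8, 8))
  for (f in plan78$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_setequal(c(f$train, f$val, f$test), subs78)
  }
  # every subject appears in exactly one test fold
  all_test <- unlist(lapply(plan78$folds, `[[`, "test"))
  expect_setequal(all_test, subs78)
  expect_equal(anyDuplicated(all_test), 0L)
  # determinism
  expect_identical(split_subjects_kfold(subs78, 10, seed = 7)$assignments,
                   plan78$assignments)
  expect_error(split_subjects_kfold(subs20, 21), "exceeds")
})

test_that("early stopping follows the traced validation sequence", {
  vals <- c(0.5, 0.6, rep(0.6, 20) - 1e-9)
  for (i in seq_along(vals)) {
    st <- mcafnet:::early_stop_status(vals[seq_len(i)], patience = 20)
    if (i < 22) expect_false(st$stop) else expect_true(st$stop)
  }
  st <- mcafnet:::early_stop_status(vals, patience = 20)
  expect_equal(st$best_pass, 2)
  # ties keep the earliest pass
  st2 <- mcafnet:::early_stop_status(c(0.4, 0.7, 0.7, 0.7), patience = 20)
  expect_equal(st2$best_pass, 2)
})

make_toy_problem <- function(n, d = 6, seed = 61) {
  set.seed(seed)
  y <- rep(stage_levels(), length.out = n)
  x <- array(rnorm(n * 3 * 4 * d), dim = c(n, 3, 4, d))
  for (i in seq_len(n)) {
    k <- match(y[i], stage_levels())
    x[i, , , k] <- x[i, , , k] + 3   # class-specific feature bump
  }
  list(x = x, y = y)
}

test_that("training returns the best-validation model and a full history", {
  toy <- make_toy_problem(60)
  cfg <- model_config(d = 6, c_channels = 3, l_frames = 4, heads = 2,
                      n_attention_layers = 1, hidden = 10, dropout = 0)
  model <- build_model(cfg, seed = 62)
  fit <- train_model(model, toy$x, toy$y, toy$x, toy$y,
                     train_config(learning_rate = 5e-3, batch_size = 16,
                                  max_epochs = 12, patience = 20, seed = 63))
  expect_s3_class(fit$history, "tbl_df")
  expect_equal(names(fit$history),
               c("pass", "train_loss", "train_acc", "val_loss", "val_acc"))
  expect_equal(fit$best_pass, which.max(fit$history$val_acc))
  # returned model reproduces the best recorded validation accuracy
  ev <- mcafnet:::evaluate_tensors(fit$model, toy$x,
                                   as.integer(factor(toy$y, levels = stage_levels())))
  expect_equal(ev$accuracy, max(fit$history$val_acc), tolerance = 1e-12)
  expect_gt(max(fit$history$val_acc), 0.8)  # separable toy problem is learned
})

test_that("identical seeds give identical training trajectories", {
  toy <- make_toy_problem(40)
  cfg <- model_config(d = 6, c_channels = 3, l_frames = 4, heads = 2,
                      n_attention_layers = 1, hidden = 8, dropout = 0.3)
  run <- function() {
    model <- build_model(cfg, seed = 64)
    train_model(model, toy$x, toy$y, toy$x, toy$y,
                train_config(learning_rate = 1e-3, batch_size = 16,
                             max_epochs = 4, seed = 65))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("prediction preserves order, is batch-size invariant, and handles empty input", {
  toy <- make_toy_problem(25)
  model <- build_model(model_config(d = 6, c_channels = 3, l_frames = 4,
                                    heads = 2, n_attention_layers = 1,
                                    hidden = 8, dropout = 0), seed = 66)
  p1 <- predict_stages(model, toy$x, batch_size = 1)
  p64 <- predict_stages(model, toy$x, batch_size = 64)
  expect_equal(p1$epoch_index, 1:25)
  expect_lt(max(abs(as.matrix(p1[, 2:6]) - as.matrix(p64[, 2:6]))), 1e-5)
  expect_identical(p1$predicted, p64$predicted)
  empty <- predict_stages(model, array(0, dim = c(0, 3, 4, 6)))
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty),
               c("epoch_index", "p_W", "p_N1", "p_N2", "p_N3", "p_REM", "predicted"))
})

test_that("fit accessors expose tidy history and summary", {
  toy <- make_toy_problem(20)
  model <- build_model(model_config(d = 6, c_channels = 3, l_frames = 4,
                                    heads = 2, n_attention_layers = 1,
                                    hidden = 8, dropout = 0), seed = 67)
  fit <- train_model(model, toy$x, toy$y, toy$x, toy$y,
                     train_config(learning_rate = 1e-3, batch_size = 10,
                                  max_epochs = 2, seed = 68))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_equal(g$passes, 2)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
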