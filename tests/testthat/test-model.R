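small_cfg <- function(...) {
  args <- utils::modifyList(
    list(d = 8, c_channels = 3, l_frames = 5, heads = 2,
         n_attention_layers = 2, hidden = 7, dropout = 0),
    list(...))
  do.call(model_config, args)
}

test_that("forward output lies on the probability simplex", {
  set.seed(51)
  model <- build_model(small_cfg(), seed = 3)
  x <- rand_tensor(c(4, 3, 5, 8))
  fwd <- model_forward(model, x)
  expect_equal(dim(fwd$probs), c(4, 5))
  expect_true(all(fwd$probs >= 0))
  expect_equal(rowSums(fwd$probs), rep(1, 4), tolerance = 1e-6)
})

test_that("a zero final layer yields the uniform distribution", {
  model <- build_model(small_cfg(), seed = 3)
  model$params$head$w2[] <- 0
  model$params$head$b2[] <- 0
  fwd <- model_forward(model, rand_tensor(c(3, 3, 5, 8), seed = 5))
  expect_equal(unname(as.vector(fwd$probs)), rep(0.2, 15))
})

test_that("evaluation-mode forward is deterministic even with dropout configured", {
  model <- build_model(small_cfg(dropout = 0.5), seed = 3)
  x <- rand_tensor(c(2, 3, 5, 8), seed = 6)
  f1 <- model_forward(model, x)
  f2 <- model_forward(model, x)
  expect_identical(f1$probs, f2$probs)
})

test_that("input shape mismatches are rejected", {
  model <- build_model(small_cfg(), seed = 3)
  expect_error(model_forward(model, rand_tensor(c(2, 2, 5, 8), seed = 1)),
               "does not match")
  expect_error(model_forward(model, rand_tensor(c(2, 3, 5, 9), seed = 1)),
               "does not match")
})

test_that("parameter counts match closed-form arithmetic across configurations", {
  closed_form <- function(d, c_n, heads, n_a, hf, k, n_cls, kern = 3, exp_f = 2) {
    tconv <- c_n * (kern * exp_f * d + exp_f * d + exp_f * d * d + d)
    fusion <- n_a * (d * 3 * d + 3 * d + d * d + d + d + 1)
    head <- c_n * d * hf + hf + hf * n_cls + n_cls
    tconv + fusion + head
  }
  grid <- list(c(8, 3, 2, 2, 7), c(16, 3, 4, 1, 12), c(32, 3, 2, 1, 128),
               c(12, 2, 3, 2, 9), c(128, 3, 4, 2, 512))
  for (g in grid) {
    model <- build_model(model_config(d = g[1], c_channels = g[2], heads = g[3],
                                      n_attention_layers = g[4], hidden = g[5]),
                         seed = 1)
    expect_equal(count_parameters(model)$total,
                 closed_form(g[1], g[2], g[3], g[4], g[5], 3, 5))
  }
  # classifier head alone at full size: (384*512 + 512) + (512*5 + 5)
  full <- build_model(model_config(), seed = 1)
  by_mod <- count_parameters(full)$by_module
  expect_equal(by_mod$parameters[by_mod$module == "head"],
               (384 * 512 + 512) + (512 * 5 + 5))
  # a single affine D -> 3D map with bias at D = 128
  expect_equal(128 * 384 + 384, 49536)
  expect_equal(length(full$params$fusion[[1]]$qkv_w) +
                 length(full$params$fusion[[1]]$qkv_b), 49536)
  # widening the hidden layer strictly increases the count
  wider <- build_model(model_config(hidden = 1024), seed = 1)
  expect_gt(count_parameters(wider)$total, count_parameters(full)$total)
})

test_that("checkpoints round-trip bit-exactly and guard against mismatch", {
  model <- build_model(small_cfg(), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path, expected_config = small_cfg())
  x <- rand_tensor(c(2, 3, 5, 8), seed = 10)
  expect_identical(model_forward(model, x)$probs,
                   model_forward(back, x)$probs)
  expect_error(load_checkpoint(path, expected_config = small_cfg(heads = 1)),
               "heads")
  # truncated file is a parse error, not silent corruption
  bytes <- readBin(path, "raw", file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".rds")
  writeBin(bytes[seq_len(20)], trunc_path)
  expect_error(load_checkpoint(trunc_path), "cannot parse")
})

test_that("gradients reach the temporal convolution through the residual path when gates are closed", {
  model <- build_model(small_cfg(), seed = 12)
  for (i in seq_along(model$params$fusion)) {
    model$params$fusion[[i]]$gate_b <- -50
  }
  x <- rand_tensor(c(3, 3, 5, 8), seed = 13)
  fwd <- model_forward(model, x, training = TRUE)
  grads <- mcafnet:::model_backward(model, fwd, c(1L, 2L, 3L))
  tnorm <- sqrt(sum(unlist(lapply(grads$tconv, function(g)
    sum(mcafnet:::params_flatten(g)^2)))))
  expect_gt(tnorm, 1e-8)
})

test_that("analytic gradients match finite differences on a small model", {
  model <- build_model(small_cfg(n_attention_layers = 1), seed = 14)
  x <- rand_tensor(c(2, 3, 5, 8), seed = 15)
  y <- c(2L, 4L)
  fwd <- model_forward(model, x, training = TRUE)
  grads <- mcafnet:::model_backward(model, fwd, y)
  loss_at <- function(m) {
    mcafnet:::cross_entropy(model_forward(m, x, training = TRUE)$probs, y)
  }
  eps <- 1e-6
  set.seed(16)
  check <- function(getter, setter, gvals) {
    idx <- sample(seq_along(gvals), min(5, length(gvals)))
    for (i in idx) {
      m2 <- model
      v <- getter(m2); v[i] <- v[i] + eps; m2 <- setter(m2, v)
      lp <- loss_at(m2)
      v[i] <- v[i] - 2 * eps; m2 <- setter(m2, v)
      lm <- loss_at(m2)
      expect_lt(abs((lp - lm) / (2 * eps) - gvals[i]), 1e-6)
    }
  }
  check(function(m) m$params$tconv[[2]]$dw_w,
        function(m, v) { m$params$tconv[[2]]$dw_w <- v; m },
        grads$tconv[[2]]$dw_w)
  check(function(m) m$params$fusion[[1]]$qkv_w,
        function(m, v) { m$params$fusion[[1]]$qkv_w <- v; m },
        grads$fusion[[1]]$qkv_w)
  check(function(m) m$params$fusion[[1]]$gate_w,
        function(m, v) { m$params$fusion[[1]]$gate_w <- v; m },
        grads$fusion[[1]]$gate_w)
  check(function(m) m$params$head$w1,
        function(m, v) { m$params$head$w1 <- v; m },
        grads$head$w1)
})

test_that("ablation variants are constructible from config alone", {
  x <- rand_tensor(c(2, 3, 5, 8), seed = 17)
  no_fusion <- build_model(small_cfg(use_fusion = FALSE), seed = 1)
  no_tconv <- build_model(small_cfg(use_temporal_conv = FALSE), seed = 1)
  single <- build_model(model_config(d = 8, c_channels = 1, l_frames = 5,
                                     heads = 2, hidden = 7, dropout = 0), seed = 1)
  expect_equal(dim(model_forward(no_fusion, x)$probs), c(2, 5))
  expect_equal(dim(model_forward(no_tconv, x)$probs), c(2, 5))
  expect_equal(dim(model_forward(single, x[, 1, , , drop = FALSE])$probs), c(2, 5))
  expect_null(no_fusion$params$fusion)
  expect_null(no_tconv$params$tconv)
})
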