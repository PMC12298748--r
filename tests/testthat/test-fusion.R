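test_that("QKV projection obeys its shape contract and simple algebra", {
  set.seed(31)
  p <- attention_init(8, heads = 4)
  x <- rand_tensor(c(1, 3, 5, 8))
  qkv <- project_qkv(x, p)
  expect_equal(dim(qkv$q), c(1, 3, 5, 4, 2))
  # zero weights give zero projections
  p0 <- p
  p0$qkv_w[] <- 0; p0$qkv_b[] <- 0
  qkv0 <- project_qkv(x, p0)
  expect_equal(unname(as.vector(qkv0$q)), rep(0, length(qkv0$q)))
  expect_equal(unname(as.vector(qkv0$v)), rep(0, length(qkv0$v)))
  # identity-block weights reproduce x in each of Q, K, V
  pid <- p
  pid$qkv_w <- cbind(diag(8), diag(8), diag(8))
  pid$qkv_b[] <- 0
  qkvi <- project_qkv(x, pid)
  fold_back <- function(a) {
    d <- dim(a)
    a <- aperm(a, c(1, 2, 3, 5, 4))
    dim(a) <- c(d[1], d[2], d[3], d[4] * d[5])
    a
  }
  expect_equal(fold_back(qkvi$q), x, tolerance = 1e-12)
  expect_equal(fold_back(qkvi$k), x, tolerance = 1e-12)
})

test_that("with one channel the mechanism reduces to standard self-attention", {
  set.seed(32)
  q <- rand_tensor(c(1, 1, 4, 2, 3))
  k <- rand_tensor(c(1, 1, 4, 2, 3))
  v <- rand_tensor(c(1, 1, 4, 2, 3))
  res <- cross_channel_attention(q, k, v)
  # textbook formula per head
  ref <- array(0, dim = c(1, 1, 4, 6))
  for (h in 1:2) {
    qs <- q[1, 1, , h, ]; ks <- k[1, 1, , h, ]; vs <- v[1, 1, , h, ]
    a <- qs %*% t(ks) / sqrt(3)
    w <- t(apply(a, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    ref[1, 1, , (h - 1) * 3 + 1:3] <- w %*% vs
  }
  expect_lt(max(abs(res$o - ref)), 1e-12)
})

test_that("constant keys give uniform weights and mean-pooled values", {
  set.seed(33)
  b <- 1; c_n <- 2; l_len <- 4; h_n <- 2; dh <- 3
  q <- rand_tensor(c(b, c_n, l_len, h_n, dh))
  k <- rand_tensor(c(b, c_n, 1, h_n, dh))[, , rep(1, l_len), , , drop = FALSE]
  dim(k) <- dim(q)
  v <- rand_tensor(c(b, c_n, l_len, h_n, dh))
  res <- cross_channel_attention(q, k, v, keep_weights = TRUE)
  expect_equal(unname(as.vector(res$weights)),
               rep(1 / l_len, length(res$weights)), tolerance = 1e-12)
  for (i in seq_len(c_n)) for (h in seq_len(h_n)) {
    # sum over key channels of the mean value vector over positions
    expected <- colSums(t(vapply(seq_len(c_n),
                                 function(j) colMeans(v[1, j, , h, ]),
                                 numeric(dh))))
    for (lq in seq_len(l_len)) {
      expect_equal(res$o[1, i, lq, (h - 1) * dh + seq_len(dh)], expected,
                   tolerance = 1e-10)
    }
  }
})

test_that("vectorized attention equals the scalar nested-loop oracle on a shape grid", {
  set.seed(34)
  for (b in 1:2) for (c_n in 1:3) for (l_len in c(1, 3, 4)) for (h_n in 1:2) {
    dh <- 4 / h_n * 1  # D = 4 total
    q <- rand_tensor(c(b, c_n, l_len, h_n, 4 / h_n))
    k <- rand_tensor(c(b, c_n, l_len, h_n, 4 / h_n))
    v <- rand_tensor(c(b, c_n, l_len, h_n, 4 / h_n))
    res <- cross_channel_attention(q, k, v)
    ref <- scalar_attention(q, k, v)
    expect_lt(max(abs(res$o - ref)), 1e-6)
  }
})

test_that("attention weights normalize per channel pair and query position", {
  set.seed(35)
  q <- rand_tensor(c(2, 3, 4, 2, 2))
  k <- rand_tensor(c(2, 3, 4, 2, 2))
  v <- rand_tensor(c(2, 3, 4, 2, 2))
  res <- cross_channel_attention(q, k, v, keep_weights = TRUE)
  w <- res$weights  # [B, H, C, C, Lq, Lk]
  expect_true(all(w >= 0 & w <= 1))
  sums <- apply(w, c(1, 2, 3, 4, 5), sum)
  expect_equal(unname(as.vector(sums)), rep(1, length(sums)), tolerance = 1e-5)
  # hence each query position receives total mass C across key channels
  mass <- apply(w, c(1, 2, 3, 5), sum)
  expect_equal(unname(as.vector(mass)), rep(3, length(mass)), tolerance = 1e-5)
})

test_that("head merge projection is the stated affine map", {
  set.seed(36)
  p <- attention_init(6, heads = 2)
  o <- rand_tensor(c(2, 2, 3, 6))
  pid <- p; pid$out_w <- diag(6); pid$out_b[] <- 0
  expect_equal(merge_heads_project(o, pid), o, tolerance = 1e-12)
  pz <- p; pz$out_w[] <- 0; pz$out_b[] <- 0
  expect_equal(unname(as.vector(merge_heads_project(o, pz))),
               rep(0, length(o)))
  got <- merge_heads_project(o, p)
  m <- matrix(o, 12, 6)
  ref <- array(m %*% p$out_w + rep(p$out_b, each = 12), dim = dim(o))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the dynamic gate matches closed-form evaluation and stays in (0,1)", {
  set.seed(37)
  p <- attention_init(5, heads = 1)
  x <- rand_tensor(c(3, 2, 4, 5))
  # zero gate -> exactly 0.5
  g0 <- dynamic_gate(x, p)
  expect_equal(g0, rep(0.5, 3))
  # strongly negative bias -> essentially closed
  pneg <- p; pneg$gate_b <- -20
  expect_equal(dynamic_gate(x, pneg), rep(1 / (1 + exp(20)), 3),
               tolerance = 1e-15)
  # constant input -> sigma(c * sum(W) + b)
  pr <- p; pr$gate_w <- rnorm(5); pr$gate_b <- 0.3
  xc <- array(0.7, dim = c(2, 2, 4, 5))
  expect_equal(dynamic_gate(xc, pr),
               rep(1 / (1 + exp(-(0.7 * sum(pr$gate_w) + 0.3))), 2),
               tolerance = 1e-12)
  # strictly inside (0,1) for random parameters
  pr$gate_b <- rnorm(1)
  g <- dynamic_gate(rand_tensor(c(4, 2, 4, 5)), pr)
  expect_true(all(g > 0 & g < 1))
})

test_that("a fusion layer is the gated residual composition of its parts", {
  set.seed(38)
  p <- attention_init(4, heads = 2)
  p$gate_w <- rnorm(4); p$gate_b <- 0.2
  x <- rand_tensor(c(2, 3, 3, 4))
  res <- fuse_layer(x, p)
  # independent composition from the public sub-operations
  qkv <- project_qkv(x, p)
  att <- cross_channel_attention(qkv$q, qkv$k, qkv$v)
  oprime <- merge_heads_project(att$o, p)
  g <- dynamic_gate(x, p)
  ref <- x
  for (bi in 1:2) ref[bi, , , ] <- x[bi, , , ] + g[bi] * oprime[bi, , , ]
  expect_lt(max(abs(res$y - ref)), 1e-10)
  # gate forced shut -> residual identity
  pshut <- p; pshut$gate_b <- -1e3
  expect_lt(max(abs(fuse_layer(x, pshut)$y - x)), 1e-6)
  # zero output projection -> y == x exactly even with the gate half-open
  pz <- p; pz$out_w[] <- 0; pz$out_b[] <- 0; pz$gate_w[] <- 0; pz$gate_b <- 0
  rz <- fuse_layer(x, pz)
  expect_equal(rz$gate, rep(0.5, 2))
  expect_identical(rz$y, x)
})

test_that("a fusion stack composes layers sequentially", {
  set.seed(39)
  p1 <- attention_init(4, heads = 2); p1$gate_w <- rnorm(4)
  p2 <- attention_init(4, heads = 2); p2$gate_w <- rnorm(4)
  x <- rand_tensor(c(2, 2, 3, 4))
  one <- fuse_stack(x, list(p1))
  expect_equal(one$y, fuse_layer(x, p1)$y, tolerance = 1e-12)
  two <- fuse_stack(x, list(p1, p2))
  manual <- fuse_layer(fuse_layer(x, p1)$y, p2)$y
  expect_equal(two$y, manual, tolerance = 1e-12)
  shut <- function(p) { p$gate_b <- -1e3; p }
  closed <- fuse_stack(x, list(shut(p1), shut(p2)))
  expect_lt(max(abs(closed$y - x)), 1e-5)
  expect_error(fuse_stack(x, list()), "at least one")
})

test_that("channel permutation of the input permutes the output channels", {
  set.seed(40)
  p <- attention_init(4, heads = 2)
  p$gate_w <- rnorm(4); p$gate_b <- -0.1
  x <- rand_tensor(c(2, 3, 3, 4))
  perm <- c(3, 1, 2)
  y <- fuse_layer(x, p)$y
  y_perm <- fuse_layer(x[, perm, , , drop = FALSE], p)$y
  expect_lt(max(abs(y_perm - y[, perm, , , drop = FALSE])), 1e-10)
})
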