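# Independent reference implementations used to check the vectorized code.
# These are deliberately written as plain nested loops over the defining
# formulas, sharing no code with the package internals.

# scalar cross-channel multi-head attention: for every head h and channel
# pair (i, j), A = Q_i K_j' / sqrt(d_h), softmax over key positions, output
# for channel i is the sum over all j of W V_j; heads concatenated.
scalar_attention <- function(q, k, v) {
  d <- dim(q)  # [B, C, L, H, dh]
  b <- d[1]; c_n <- d[2]; l_len <- d[3]; h_n <- d[4]; dh <- d[5]
  out <- array(0, dim = c(b, c_n, l_len, h_n * dh))
  for (bi in seq_len(b)) for (hi in seq_len(h_n)) for (i in seq_len(c_n)) {
    acc <- matrix(0, l_len, dh)
    for (j in seq_len(c_n)) {
      a <- matrix(0, l_len, l_len)
      for (lq in seq_len(l_len)) for (lk in seq_len(l_len)) {
        a[lq, lk] <- sum(q[bi, i, lq, hi, ] * k[bi, j, lk, hi, ]) / sqrt(dh)
      }
      w <- t(apply(a, 1, function(row) exp(row - max(row)) / sum(exp(row - max(row)))))
      if (l_len == 1) w <- matrix(w, 1, 1)
      for (lq in seq_len(l_len)) for (dd in seq_len(dh)) {
        acc[lq, dd] <- acc[lq, dd] + sum(w[lq, ] * v[bi, j, , hi, dd])
      }
    }
    out[bi, i, , (hi - 1) * dh + seq_len(dh)] <- acc
  }
  out
}

# naive per-position grouped widening convolution + GELU + 1x1 reduction
naive_temporal_conv <- function(x, params, kernel = 3, expansion = 2) {
  d <- dim(x)  # [B, L, D]
  half <- (kernel - 1) / 2
  gelu_ref <- function(z) z * pnorm(z)
  out <- array(0, dim = d)
  for (bi in seq_len(d[1])) for (l in seq_len(d[2])) {
    u <- numeric(expansion * d[3])
    for (e in seq_len(expansion)) for (feat in seq_len(d[3])) {
      m <- (e - 1) * d[3] + feat
      s <- params$dw_b[m]
      for (kk in seq_len(kernel)) {
        lsrc <- l + kk - 1 - half
        if (lsrc >= 1 && lsrc <= d[2]) {
          s <- s + x[bi, lsrc, feat] * params$dw_w[kk, m]
        }
      }
      u[m] <- s
    }
    out[bi, l, ] <- as.numeric(gelu_ref(u) %*% params$pw_w) + params$pw_b
  }
  out
}

# hand-coded AdamW with decoupled weight decay, scalar-by-scalar
reference_adamw <- function(theta0, grad_fn, steps, lr, wd, b1, b2, eps) {
  theta <- theta0
  m <- theta * 0
  v <- theta * 0
  for (t in seq_len(steps)) {
    g <- grad_fn(theta)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    theta <- theta - lr * wd * theta - lr * mhat / (sqrt(vhat) + eps)
  }
  theta
}

# power in a frequency band of one signal, from the raw periodogram
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= hi
  sum(p[sel])
}

rand_tensor <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}

tiny_model <- function(..., seed = 11) {
  build_model(model_config(...), seed = seed)
}
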