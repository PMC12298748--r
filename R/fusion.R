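#' Initialize parameters for one cross-channel attention fusion layer
#'
#' One layer holds a shared position-wise QKV projection (D -> 3D), an
#' output projection (D -> D), and a scalar gate (linear layer on the
#' global mean feature followed by a sigmoid). Projections are shared
#' across channels and positions.
#'
#' @param d Feature dimension D.
#' @param heads Number of attention heads H; must divide D.
#' @return Parameter list `qkv_w` `[D x 3D]`, `qkv_b` `[3D]`, `out_w`
#'   `[D x D]`, `out_b` `[D]`, `gate_w` `[D]`, `gate_b` scalar, plus `heads`.
#' @export
attention_init <- function(d, heads = 4) {
  if (d %% heads != 0) abort("feature dimension must be divisible by the head count")
  lim <- sqrt(6 / (2 * d))
  list(qkv_w = matrix(runif(d * 3 * d, -lim, lim), d, 3 * d),
       qkv_b = numeric(3 * d),
       out_w = matrix(runif(d * d, -lim, lim), d, d),
       out_b = numeric(d),
       gate_w = numeric(d),
       gate_b = 0,
       heads = heads)
}

# flatten [B, C, L, D] to [(B*C*L) x D]; row index runs b fastest, then c, then l
flatten_bcld <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

unflatten_bcld <- function(m, b, c_n, l_len, d_feat) {
  dim(m) <- c(b, c_n, l_len, d_feat)
  m
}

#' Project a fused-input tensor into queries, keys and values
#'
#' Applies the shared position-wise affine map to 3D features and splits
#' into Q, K, V, each reshaped into H heads of `D/H` features.
#'
#' @param x Array `[B x C x L x D]`.
#' @param p Parameters from [attention_init()].
#' @return List `q`, `k`, `v`, each an array `[B x C x L x H x d_h]`.
#' @export
project_qkv <- function(x, p) {
  d <- dim(x)
  if (d[4] != nrow(p$qkv_w)) abort("feature dimension does not match QKV weights")
  h <- p$heads
  dh <- d[4] %/% h
  m <- flatten_bcld(x)
  qkv <- m %*% p$qkv_w + rep(p$qkv_b, each = nrow(m))
  split_one <- function(block) {
    a <- unflatten_bcld(block, d[1], d[2], d[3], d[4])
    dim(a) <- c(d[1], d[2], d[3], dh, h)   # head index is the slow feature axis
    aperm(a, c(1, 2, 3, 5, 4))
  }
  list(q = split_one(qkv[, seq_len(d[4]), drop = FALSE]),
       k = split_one(qkv[, d[4] + seq_len(d[4]), drop = FALSE]),
       v = split_one(qkv[, 2 * d[4] + seq_len(d[4]), drop = FALSE]))
}

# core attention over stacked channel-position rows. For one sample and one
# head, rows of q/k/v [C*L x d_h] are ordered channel-fastest; the score
# matrix q %*% t(k) then reshapes to [C, L, C, L] = (query channel, query
# position, key channel, key position), and softmax is taken per channel
# pair over key positions. Multiplying the blockwise-normalized weight
# matrix back into v sums the per-pair outputs over all key channels.
attention_bh <- function(qb, kb, vb, c_n, l_len) {
  dh <- ncol(qb)
  s <- tcrossprod(qb, kb) / sqrt(dh)
  if (!all(is.finite(s))) abort("non-finite attention scores")
  dim(s) <- c(c_n * l_len * c_n, l_len)
  w <- softmax_rows(s)
  dim(w) <- c(c_n * l_len, c_n * l_len)
  list(o = w %*% vb, w = w)
}

attention_bh_backward <- function(do_b, w, qb, kb, vb, c_n, l_len) {
  dh <- ncol(qb)
  dv <- crossprod(w, do_b)
  dw <- tcrossprod(do_b, vb)
  dim(dw) <- c(c_n * l_len * c_n, l_len)
  dim(w) <- c(c_n * l_len * c_n, l_len)
  ds <- w * (dw - rowSums(dw * w))
  dim(ds) <- c(c_n * l_len, c_n * l_len)
  dim(w) <- c(c_n * l_len, c_n * l_len)
  dq <- (ds %*% kb) / sqrt(dh)
  dk <- crossprod(ds, qb) / sqrt(dh)
  list(dq = dq, dk = dk, dv = dv)
}

# head-major core: q/k/v as [C*L, dh, H, B] (rows channel-fastest); runs the
# per-(sample, head) attention and returns o in the same layout
attention_core <- function(qm, km, vm, c_n, l_len, keep_weights = FALSE) {
  dmn <- dim(qm)
  dh <- dmn[2]; h <- dmn[3]; b <- dmn[4]
  o <- array(0, dim = dmn)
  wmaps <- if (keep_weights) array(0, dim = c(b, h, c_n, c_n, l_len, l_len)) else NULL
  wcache <- vector("list", b * h)
  slice <- function(a, hi, bi) matrix(a[, , hi, bi], c_n * l_len, dh)
  for (bi in seq_len(b)) {
    for (hi in seq_len(h)) {
      res <- attention_bh(slice(qm, hi, bi), slice(km, hi, bi),
                          slice(vm, hi, bi), c_n, l_len)
      o[, , hi, bi] <- res$o
      wcache[[(bi - 1L) * h + hi]] <- res$w
      if (keep_weights) {
        wr <- res$w
        dim(wr) <- c(c_n, l_len, c_n, l_len)
        wmaps[bi, hi, , , , ] <- aperm(wr, c(1, 3, 2, 4))
      }
    }
  }
  list(o = o, weights = wmaps, wcache = wcache)
}

attention_core_backward <- function(do_m, wcache, qm, km, vm, c_n, l_len) {
  dmn <- dim(qm)
  dh <- dmn[2]; h <- dmn[3]; b <- dmn[4]
  dq <- array(0, dim = dmn); dk <- dq; dv <- dq
  slice <- function(a, hi, bi) matrix(a[, , hi, bi], c_n * l_len, dh)
  for (bi in seq_len(b)) {
    for (hi in seq_len(h)) {
      res <- attention_bh_backward(slice(do_m, hi, bi),
                                   wcache[[(bi - 1L) * h + hi]],
                                   slice(qm, hi, bi), slice(km, hi, bi),
                                   slice(vm, hi, bi), c_n, l_len)
      dq[, , hi, bi] <- res$dq
      dk[, , hi, bi] <- res$dk
      dv[, , hi, bi] <- res$dv
    }
  }
  list(dq = dq, dk = dk, dv = dv)
}

# [(B*C*L) x D] column block -> head-major [C*L, dh, H, B]
block_head_major <- function(block, b, c_n, l_len, dh, h) {
  dim(block) <- c(b, c_n, l_len, dh, h)
  block <- aperm(block, c(2, 3, 4, 5, 1))
  dim(block) <- c(c_n * l_len, dh, h, b)
  block
}

# head-major [C*L, dh, H, B] -> [(B*C*L) x D]
head_major_to_flat <- function(a, b, c_n, l_len, dh, h) {
  dim(a) <- c(c_n, l_len, dh, h, b)
  a <- aperm(a, c(5, 1, 2, 3, 4))
  dim(a) <- c(b * c_n * l_len, dh * h)
  a
}

# rearrange a head tensor [B, C, L, H, dh] into [C*L, dh, H, B] so that
# per-(sample, head) slices are contiguous matrices with channel-fastest rows
head_major <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(2, 3, 5, 4, 1))
  dim(m) <- c(d[2] * d[3], d[5], d[4], d[1])
  m
}

#' Cross-channel multi-head attention
#'
#' For every head and every ordered channel pair (query channel i, key
#' channel j), scaled dot-product scores between all temporal positions are
#' softmax-normalized over key positions; the weighted values are summed
#' over all key channels (including j = i) and heads are concatenated back
#' to D features.
#'
#' @param q,k,v Arrays `[B x C x L x H x d_h]` from [project_qkv()].
#' @param keep_weights If `TRUE`, also return the attention weights as an
#'   array `[B x H x C x C x L x L]` (query channel, key channel, query
#'   position, key position).
#' @return List with `o` (array `[B x C x L x D]`) and `weights` (or `NULL`).
#' @export
cross_channel_attention <- function(q, k, v, keep_weights = FALSE) {
  d <- dim(q)
  if (!identical(d, dim(k)) || !identical(d, dim(v))) abort("Q/K/V shapes differ")
  b <- d[1]; c_n <- d[2]; l_len <- d[3]; h <- d[4]; dh <- d[5]
  qm <- head_major(q); km <- head_major(k); vm <- head_major(v)
  res <- attention_core(qm, km, vm, c_n, l_len, keep_weights)
  oo <- head_major_to_flat(res$o, b, c_n, l_len, dh, h)
  dim(oo) <- c(b, c_n, l_len, dh * h)
  list(o = oo, weights = res$weights)
}

#' Merge attention heads through the output projection
#'
#' Position-wise affine map of the concatenated-head attention output by the
#' learnable matrix `W_O` and bias.
#'
#' @param o Array `[B x C x L x D]`.
#' @param p Parameters from [attention_init()].
#' @return Array `[B x C x L x D]`.
#' @export
merge_heads_project <- function(o, p) {
  d <- dim(o)
  if (d[4] != nrow(p$out_w)) abort("feature dimension does not match output weights")
  m <- flatten_bcld(o)
  unflatten_bcld(m %*% p$out_w + rep(p$out_b, each = nrow(m)),
                 d[1], d[2], d[3], d[4])
}

#' Dynamic per-sample gate
#'
#' Compresses each sample's tensor to a global D-vector by averaging over
#' the channel and time axes, then maps it through a linear layer and a
#' sigmoid to one scalar gate in (0, 1) per sample.
#'
#' @param x Array `[B x C x L x D]`.
#' @param p Parameters from [attention_init()].
#' @return Numeric vector of length B.
#' @export
dynamic_gate <- function(x, p) {
  d <- dim(x)
  xm <- gate_mean(x)
  as.numeric(sigmoid(xm %*% p$gate_w + p$gate_b))
}

# mean over channel and time axes -> [B x D]
gate_mean <- function(x) {
  d <- dim(x)
  cl <- d[2] * d[3]
  a <- array(x, dim = c(d[1], cl, d[4]))
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(cl, d[1] * d[4])
  matrix(colMeans(a), d[1], d[4])
}

#' One dynamically gated cross-channel fusion layer
#'
#' Composes [project_qkv()], [cross_channel_attention()],
#' [merge_heads_project()] and [dynamic_gate()], and adds the gated
#' attention branch back onto the input: `y = x + G * O'` with the scalar
#' gate broadcast per sample.
#'
#' @param x Array `[B x C x L x D]`.
#' @param p Parameters from [attention_init()].
#' @param keep_weights Retain attention weights (see
#'   [cross_channel_attention()]).
#' @param training If `TRUE`, return a cache for backpropagation.
#' @return List `y` (same shape as `x`), `weights`, `gate` (vector of B
#'   gate values), and `cache` when training.
#' @export
fuse_layer <- function(x, p, keep_weights = FALSE, training = FALSE) {
  d <- dim(x)
  b <- d[1]; c_n <- d[2]; l_len <- d[3]; dd <- d[4]
  h <- p$heads; dh <- dd %/% h
  if (dd != nrow(p$qkv_w)) abort("feature dimension does not match QKV weights")
  m <- flatten_bcld(x)
  qkv <- m %*% p$qkv_w + rep(p$qkv_b, each = nrow(m))
  qm <- block_head_major(qkv[, seq_len(dd), drop = FALSE], b, c_n, l_len, dh, h)
  km <- block_head_major(qkv[, dd + seq_len(dd), drop = FALSE], b, c_n, l_len, dh, h)
  vm <- block_head_major(qkv[, 2 * dd + seq_len(dd), drop = FALSE], b, c_n, l_len, dh, h)
  att <- attention_core(qm, km, vm, c_n, l_len, keep_weights)
  oflat <- head_major_to_flat(att$o, b, c_n, l_len, dh, h)
  opm <- oflat %*% p$out_w + rep(p$out_b, each = nrow(m))
  xm <- gate_mean(x)
  u <- as.numeric(xm %*% p$gate_w + p$gate_b)
  g <- sigmoid(u)
  gfull <- rep(g, times = c_n * l_len)
  y <- x + array(gfull * opm, dim = d)
  cache <- if (training) {
    list(m = m, xm = xm, g = g, oflat = oflat, opm = opm,
         wcache = att$wcache, qm = qm, km = km, vm = vm)
  } else NULL
  list(y = y, weights = att$weights, gate = g, cache = cache)
}

fuse_layer_backward <- function(dy, p, cache) {
  d <- dim(dy)
  b <- d[1]; c_n <- d[2]; l_len <- d[3]; dd <- d[4]
  h <- p$heads; dh <- dd %/% h
  cl <- c_n * l_len
  dym <- flatten_bcld(dy)
  gfull <- rep(cache$g, times = cl)
  # gate branch
  dg <- rowSums(array(dym * cache$opm, dim = c(b, cl * dd)))
  du <- dg * cache$g * (1 - cache$g)
  g_gate_w <- as.numeric(crossprod(cache$xm, du))
  g_gate_b <- sum(du)
  dxm <- outer(du, p$gate_w)                       # [B x D]
  dx_gate <- array(dxm[rep(seq_len(b), times = cl), , drop = FALSE] / cl, dim = d)
  # attention branch
  dop <- gfull * dym                                # d O'
  g_out_w <- crossprod(cache$oflat, dop)
  g_out_b <- colSums(dop)
  do_flat <- tcrossprod(dop, p$out_w)
  do_m <- block_head_major(do_flat, b, c_n, l_len, dh, h)
  datt <- attention_core_backward(do_m, cache$wcache, cache$qm, cache$km,
                                  cache$vm, c_n, l_len)
  dqkv <- cbind(head_major_to_flat(datt$dq, b, c_n, l_len, dh, h),
                head_major_to_flat(datt$dk, b, c_n, l_len, dh, h),
                head_major_to_flat(datt$dv, b, c_n, l_len, dh, h))
  g_qkv_w <- crossprod(cache$m, dqkv)
  g_qkv_b <- colSums(dqkv)
  dx <- dy + dx_gate + array(tcrossprod(dqkv, p$qkv_w), dim = d)
  list(dx = dx,
       grads = list(qkv_w = g_qkv_w, qkv_b = g_qkv_b,
                    out_w = g_out_w, out_b = g_out_b,
                    gate_w = g_gate_w, gate_b = g_gate_b,
                    heads = 0))
}

#' Stack of fusion layers
#'
#' Applies [fuse_layer()] sequentially, each layer with its own independent
#' parameters, and collects every layer's attention maps.
#'
#' @param x Array `[B x C x L x D]`.
#' @param params_list Nonempty list of [attention_init()] parameter sets.
#' @param keep_weights Retain attention weights per layer.
#' @return List `y`, `weights` (list per layer), `gates` (matrix layers x B).
#' @export
fuse_stack <- function(x, params_list, keep_weights = FALSE) {
  if (length(params_list) == 0) abort("fusion stack needs at least one layer")
  weights <- vector("list", length(params_list))
  gates <- matrix(0, length(params_list), dim(x)[1])
  for (i in seq_along(params_list)) {
    res <- fuse_layer(x, params_list[[i]], keep_weights = keep_weights)
    x <- res$y
    weights[[i]] <- res$weights
    gates[i, ] <- res$gate
  }
  list(y = x, weights = weights, gates = gates)
}
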