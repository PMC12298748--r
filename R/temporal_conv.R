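#' Initialize parameters for one temporal convolution module
#'
#' The module widens the feature dimension with a depthwise 1-D convolution
#' along time (groups equal to the feature dimension, channel multiplier
#' given by `expansion`), applies GELU, then projects back down with a 1x1
#' convolution. Kernel taps use He-style scaled uniform initialization.
#'
#' @param d Feature dimension D.
#' @param kernel Odd kernel length (default 3); padding `(kernel-1)/2`
#'   preserves the sequence length.
#' @param expansion Output-channel multiplier of the depthwise stage.
#' @param dense If `TRUE`, use a dense (non-grouped) widening convolution
#'   instead of the depthwise-separable form.
#' @return Parameter list with `dw_w` `[kernel x (expansion*D)]` (or
#'   `[kernel x D x expansion*D]` when dense), `dw_b`, `pw_w`
#'   `[(expansion*D) x D]`, `pw_b`.
#' @export
temporal_conv_init <- function(d, kernel = 3, expansion = 2, dense = FALSE) {
  if (kernel %% 2 != 1) abort("kernel length must be odd")
  d2 <- expansion * d
  if (dense) {
    lim <- sqrt(6 / (kernel * d))
    dw_w <- array(runif(kernel * d * d2, -lim, lim), dim = c(kernel, d, d2))
  } else {
    lim <- sqrt(6 / kernel)
    dw_w <- matrix(runif(kernel * d2, -lim, lim), kernel, d2)
  }
  lim2 <- sqrt(6 / d2)
  list(dw_w = dw_w,
       dw_b = numeric(d2),
       pw_w = matrix(runif(d2 * d, -lim2, lim2), d2, d),
       pw_b = numeric(d))
}

# build shifted copies of a stacked sequence matrix x [(L*B) x D] whose rows
# are contiguous length-L blocks per sample; shift = -1 gives x_{l-1} with
# zero padding at each block start, +1 gives x_{l+1} zero-padded at block ends
shift_blocks <- function(x, shift, l_len, n_blocks) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  if (shift == 0) return(x)
  if (shift < 0) {
    out[-1, ] <- x[-n, ]
    out[(seq_len(n_blocks) - 1L) * l_len + 1L, ] <- 0
  } else {
    out[-n, ] <- x[-1, ]
    out[seq_len(n_blocks) * l_len, ] <- 0
  }
  out
}

# forward for one channel's stacked input xs [(L*B) x D]; returns output and
# cache for the backward pass
temporal_conv_channel_forward <- function(xs, params, l_len, n_blocks,
                                          kernel, expansion, dense = FALSE) {
  d <- ncol(xs)
  d2 <- expansion * d
  half <- (kernel - 1L) %/% 2L
  shifts <- lapply(seq_len(kernel) - 1L - half, shift_blocks,
                   x = xs, l_len = l_len, n_blocks = n_blocks)
  u <- matrix(rep(params$dw_b, each = nrow(xs)), nrow(xs), d2)
  if (dense) {
    for (k in seq_len(kernel)) u <- u + shifts[[k]] %*% params$dw_w[k, , ]
  } else {
    for (e in seq_len(expansion)) {
      cols <- (e - 1L) * d + seq_len(d)
      for (k in seq_len(kernel)) {
        u[, cols] <- u[, cols] + colscale(shifts[[k]], params$dw_w[k, cols])
      }
    }
  }
  pn <- pnorm(u)
  a <- u * pn
  y <- a %*% params$pw_w + rep(params$pw_b, each = nrow(xs))
  list(y = y, cache = list(shifts = shifts, u = u, a = a, pn = pn))
}

temporal_conv_channel_backward <- function(dy, params, cache, l_len, n_blocks,
                                           kernel, expansion, dense = FALSE) {
  d <- ncol(dy)
  d2 <- expansion * d
  half <- (kernel - 1L) %/% 2L
  da <- tcrossprod(dy, params$pw_w)
  g <- list(pw_w = crossprod(cache$a, dy),
            pw_b = colSums(dy))
  du <- da * (cache$pn + cache$u * dnorm(cache$u))
  g$dw_b <- colSums(du)
  dx <- matrix(0, nrow(dy), d)
  if (dense) {
    g$dw_w <- array(0, dim = c(kernel, d, d2))
    for (k in seq_len(kernel)) {
      g$dw_w[k, , ] <- t(cache$shifts[[k]]) %*% du
      # transpose of forward shift: contribution flows back with opposite shift
      dx <- dx + shift_blocks(du %*% t(params$dw_w[k, , ]),
                              -(k - 1L - half), l_len, n_blocks)
    }
  } else {
    g$dw_w <- matrix(0, kernel, d2)
    for (e in seq_len(expansion)) {
      cols <- (e - 1L) * d + seq_len(d)
      for (k in seq_len(kernel)) {
        g$dw_w[k, cols] <- colSums(cache$shifts[[k]] * du[, cols])
        dx <- dx + shift_blocks(colscale(du[, cols, drop = FALSE],
                                         params$dw_w[k, cols]),
                                -(k - 1L - half), l_len, n_blocks)
      }
    }
  }
  list(dx = dx, grads = g[c("dw_w", "dw_b", "pw_w", "pw_b")])
}

# reshape helpers between [B, C, L, D] arrays and per-channel stacked
# matrices [(L*B) x D] with contiguous per-sample blocks
channel_stack <- function(x, c_i) {
  d <- dim(x)
  xc <- x[, c_i, , , drop = FALSE]
  dim(xc) <- d[c(1, 3, 4)]
  m <- aperm(xc, c(2, 1, 3))
  dim(m) <- c(d[3] * d[1], d[4])
  m
}

channel_unstack <- function(m, b, l_len, d_feat) {
  dim(m) <- c(l_len, b, d_feat)
  aperm(m, c(2, 1, 3))
}

#' Apply a temporal convolution to one sequence batch
#'
#' @param x Array `[B x L x D]`.
#' @param params Parameters from [temporal_conv_init()].
#' @param kernel,expansion,dense Must match the parameter shapes.
#' @return Array `[B x L x D]` of the same shape as the input.
#' @export
temporal_conv_forward <- function(x, params, kernel = 3, expansion = 2,
                                  dense = FALSE) {
  d <- dim(x)
  if (length(d) != 3) abort("expected an array [B x L x D]")
  if ((!dense && ncol(params$dw_w) != expansion * d[3]) ||
      nrow(params$pw_w) != expansion * d[3] || ncol(params$pw_w) != d[3]) {
    abort("parameter shapes do not match feature dimension")
  }
  m <- aperm(x, c(2, 1, 3))
  dim(m) <- c(d[2] * d[1], d[3])
  res <- temporal_conv_channel_forward(m, params, d[2], d[1], kernel, expansion, dense)
  channel_unstack(res$y, d[1], d[2], d[3])
}

#' Apply per-channel temporal convolutions
#'
#' Each signal channel is processed by its own parameter set; channels never
#' mix at this stage.
#'
#' @param x Array `[B x C x L x D]`.
#' @param params_list List of `C` parameter sets from [temporal_conv_init()].
#' @param kernel,expansion,dense Convolution configuration.
#' @return Array `[B x C x L x D]`.
#' @export
per_channel_apply <- function(x, params_list, kernel = 3, expansion = 2,
                              dense = FALSE) {
  d <- dim(x)
  if (length(d) != 4) abort("expected an array [B x C x L x D]")
  if (d[2] != length(params_list)) {
    abort(sprintf("channel count %d does not match %d parameter sets",
                  d[2], length(params_list)))
  }
  out <- array(0, dim = d)
  for (c_i in seq_len(d[2])) {
    m <- channel_stack(x, c_i)
    res <- temporal_conv_channel_forward(m, params_list[[c_i]], d[3], d[1],
                                         kernel, expansion, dense)
    out[, c_i, , ] <- channel_unstack(res$y, d[1], d[3], d[4])
  }
  out
}
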