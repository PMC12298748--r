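#' @importFrom stats pnorm dnorm rnorm runif rpois fft mvfft setNames
#' @importFrom rlang abort warn .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Canonical sleep stage order
#'
#' Class order used everywhere in the package: wake, the three NREM depths,
#' then REM. Confusion matrices, probability columns and factor levels all
#' follow this order.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

# coerce labels to the canonical stage factor, erroring on anything else
as_stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), stage_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = stage_levels())
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) abort(paste0(what, " contains non-finite values"))
  invisible(x)
}

# exact GELU (Gaussian error linear unit) and its derivative
gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# scale the columns of a matrix by a vector (faster than sweep for hot paths)
colscale <- function(m, v) m * rep(v, each = nrow(m))

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# row-wise softmax of a matrix, numerically stabilized
softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# recursive map over parallel parameter trees (lists of arrays)
params_map <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1L]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      out[[i]] <- do.call(params_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

params_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, params_flatten), use.names = FALSE) else as.numeric(p)
}

params_count <- function(p) length(params_flatten(p))

# derive a stream of well-separated child seeds from one root seed
# (kept below 2^31 so they remain valid R integers)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483629)
}
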