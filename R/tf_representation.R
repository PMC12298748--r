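#' Construct a single polysomnography epoch record
#'
#' An epoch record is the classification unit: one 30 s multi-channel signal
#' segment with its (optional) stage label and subject identifier. Signals
#' are stored channels-by-samples in microvolts.
#'
#' @param signals Numeric matrix, channels x samples (default 3 x 3000).
#' @param sampling_rate Sampling rate in Hz (default 100). The number of
#'   samples must equal `sampling_rate * 30` exactly.
#' @param label Stage label in `stage_levels()`, or `NA` if unscored.
#' @param subject_id Opaque subject identifier.
#' @param epoch_index Nonnegative integer position within the recording.
#' @return An object of class `epoch_record`.
#' @export
epoch_record <- function(signals, sampling_rate = 100, label = NA,
                         subject_id = "S0", epoch_index = 0L) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1L)
  check_finite(signals, "signals")
  s_expected <- sampling_rate * 30
  if (ncol(signals) != s_expected) {
    abort(sprintf("epoch must contain exactly %d samples (%g Hz x 30 s), got %d",
                  s_expected, sampling_rate, ncol(signals)))
  }
  if (epoch_index < 0) abort("epoch_index must be nonnegative")
  if (!is.na(label)) label <- as.character(as_stage_factor(label))
  structure(
    list(signals = signals, sampling_rate = sampling_rate, label = label,
         subject_id = as.character(subject_id), epoch_index = as.integer(epoch_index)),
    class = "epoch_record"
  )
}

#' @export
print.epoch_record <- function(x, ...) {
  cat(sprintf("<epoch_record> %d channel(s) x %d samples @ %g Hz, stage %s, subject %s, index %d\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate,
              ifelse(is.na(x$label), "?", x$label), x$subject_id, x$epoch_index))
  invisible(x)
}

#' Short-time Fourier transform configuration
#'
#' Defaults follow the standard sleep-spectrogram recipe: a 256-point FFT
#' over 2 s Hamming windows with 50% overlap, log power with a small
#' additive floor, and a reduction of the 129 one-sided bins to 128.
#'
#' @param n_fft FFT length in points.
#' @param window_seconds Analysis window length in seconds.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @param window_kind Window shape; `"hamming"` (periodic) or `"hann"`.
#' @param log_epsilon Floor added to power before taking the natural log.
#' @param bin_reduction Which of the 129 one-sided bins to drop:
#'   `"drop_nyquist"` (default) or `"drop_dc"`.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(n_fft = 256, window_seconds = 2, overlap_fraction = 0.5,
                        window_kind = c("hamming", "hann"),
                        log_epsilon = 1e-10,
                        bin_reduction = c("drop_nyquist", "drop_dc")) {
  window_kind <- match.arg(window_kind)
  bin_reduction <- match.arg(bin_reduction)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("overlap_fraction must be in [0, 1)")
  }
  structure(
    list(n_fft = as.integer(n_fft), window_seconds = window_seconds,
         overlap_fraction = overlap_fraction, window_kind = window_kind,
         log_epsilon = log_epsilon, bin_reduction = bin_reduction),
    class = "stft_config"
  )
}

# periodic window of length n
make_window <- function(kind, n) {
  k <- 0:(n - 1)
  switch(kind,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
         hann = 0.5 - 0.5 * cos(2 * pi * k / n),
         abort(paste0("unknown window kind: ", kind)))
}

#' Log-power spectrogram of a multi-channel epoch
#'
#' Frames each channel with hop `window * (1 - overlap)` and no padding at
#' the epoch edges, applies the analysis window, zero-pads each frame to
#' `n_fft` points, and returns the natural log of (one-sided power +
#' `log_epsilon`). With the defaults on a 3000-sample epoch this yields
#' 29 frames of 129 bins per channel.
#'
#' @param epoch An [epoch_record()].
#' @param cfg An [stft_config()].
#' @return Numeric array `[channels x frames x bins]` with `bins = n_fft/2 + 1`,
#'   with attributes `frequencies_hz` and `frame_times_s`.
#' @export
stft_log_power <- function(epoch, cfg = stft_config()) {
  stopifnot(inherits(epoch, "epoch_record"), inherits(cfg, "stft_config"))
  fs <- epoch$sampling_rate
  win <- as.integer(round(cfg$window_seconds * fs))
  if (win > cfg$n_fft) abort("window length exceeds n_fft")
  hop <- as.integer(round(win * (1 - cfg$overlap_fraction)))
  if (hop < 1) abort("hop must be at least one sample")
  s <- ncol(epoch$signals)
  if (s < win) abort("epoch too short")
  check_finite(epoch$signals, "signals")
  n_frames <- (s - win) %/% hop + 1L
  n_bins <- cfg$n_fft %/% 2L + 1L
  w <- make_window(cfg$window_kind, win)
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  out <- array(NA_real_, dim = c(nrow(epoch$signals), n_frames, n_bins))
  for (c_i in seq_len(nrow(epoch$signals))) {
    frames <- matrix(epoch$signals[c_i, idx], nrow = win) * w
    padded <- rbind(frames, matrix(0, cfg$n_fft - win, n_frames))
    spec <- mvfft(padded)[seq_len(n_bins), , drop = FALSE]
    power <- Mod(spec)^2
    out[c_i, , ] <- t(log(power + cfg$log_epsilon))
  }
  attr(out, "frequencies_hz") <- (seq_len(n_bins) - 1) * fs / cfg$n_fft
  attr(out, "frame_times_s") <- ((seq_len(n_frames) - 1L) * hop + win / 2) / fs
  out
}

#' Reduce the one-sided spectrum to a power-of-two bin count
#'
#' A 256-point one-sided spectrum has 129 bins; the model feature dimension
#' is 128, so exactly one bin is dropped. By default the Nyquist bin is
#' removed; `"drop_dc"` removes the DC bin instead.
#'
#' @param spec Array `[C x T x (n_fft/2 + 1)]` from [stft_log_power()].
#' @param rule `"drop_nyquist"` or `"drop_dc"`.
#' @return Array `[C x T x (bins - 1)]`, remaining bins in original order.
#' @export
reduce_bins <- function(spec, rule = c("drop_nyquist", "drop_dc")) {
  rule <- match.arg(rule)
  d <- dim(spec)
  if (length(d) != 3 || d[3] %% 2L != 1L) {
    abort("expected an array [C x T x bins] with an odd one-sided bin count")
  }
  keep <- if (rule == "drop_nyquist") seq_len(d[3] - 1L) else seq(2L, d[3])
  freqs <- attr(spec, "frequencies_hz")
  out <- spec[, , keep, drop = FALSE]
  if (!is.null(freqs)) attr(out, "frequencies_hz") <- freqs[keep]
  attr(out, "frame_times_s") <- attr(spec, "frame_times_s")
  out
}

#' Standardize a time-frequency tensor per channel
#'
#' For each channel, subtracts the mean and divides by the population
#' standard deviation computed over all time-frequency elements of that
#' channel's matrix, yielding zero mean and unit variance per channel.
#'
#' @param tf Array `[C x T x F]`.
#' @return Standardized array of the same shape.
#' @export
standardize <- function(tf) {
  check_finite(tf, "time-frequency tensor")
  d <- dim(tf)
  if (length(d) != 3) abort("expected an array [C x T x F]")
  out <- tf
  for (c_i in seq_len(d[1])) {
    m <- tf[c_i, , ]
    mu <- mean(m)
    sd_pop <- sqrt(mean((m - mu)^2))
    if (sd_pop == 0) abort("degenerate channel: zero variance")
    out[c_i, , ] <- (m - mu) / sd_pop
  }
  out
}

# average adjacent frequency bins so that F becomes `n_out` (F %% n_out == 0);
# used to build reduced-dimension models
pool_bins <- function(tf, n_out) {
  d <- dim(tf)
  if (d[3] %% n_out != 0) abort("bin count not divisible by requested feature count")
  fac <- d[3] %/% n_out
  grp <- rep(seq_len(n_out), each = fac)
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (g in seq_len(n_out)) {
    out[, , g] <- apply(tf[, , grp == g, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Convert raw epochs to a standardized spectrogram tensor stack
#'
#' Runs the full representation pipeline ([stft_log_power()],
#' [reduce_bins()], optional frequency-bin pooling, [standardize()]) over a
#' list of epochs and stacks the results into one array.
#'
#' @param epochs List of [epoch_record()]s (e.g. `generate_dataset()$epochs`).
#' @param cfg An [stft_config()].
#' @param feature_bins Optional reduced feature dimension; adjacent frequency
#'   bins are averaged in equal groups before standardization (must divide
#'   the post-reduction bin count, 128 by default).
#' @param scope Standardization scope: `"epoch"` (each epoch's channel matrix
#'   on its own, the default) or `"recording"` (moments pooled over all
#'   epochs of a subject).
#' @return List with `tf` (array `[N x C x T x F]`), `labels` (stage factor,
#'   `NA` where unscored), `subjects` (character), and `config`.
#' @export
preprocess_epochs <- function(epochs, cfg = stft_config(), feature_bins = NULL,
                              scope = c("epoch", "recording")) {
  scope <- match.arg(scope)
  if (length(epochs) == 0) abort("no epochs to preprocess")
  one <- function(ep) {
    x <- reduce_bins(stft_log_power(ep, cfg), cfg$bin_reduction)
    if (!is.null(feature_bins)) x <- pool_bins(x, feature_bins)
    x
  }
  raw <- lapply(epochs, one)
  d <- dim(raw[[1]])
  tf <- array(0, dim = c(length(raw), d))
  subjects <- vapply(epochs, function(e) e$subject_id, character(1))
  if (scope == "epoch") {
    for (i in seq_along(raw)) tf[i, , , ] <- standardize(raw[[i]])
  } else {
    for (sub in unique(subjects)) {
      sel <- which(subjects == sub)
      for (c_i in seq_len(d[1])) {
        vals <- unlist(lapply(raw[sel], function(r) r[c_i, , ]))
        mu <- mean(vals)
        sd_pop <- sqrt(mean((vals - mu)^2))
        if (sd_pop == 0) abort("degenerate channel: zero variance")
        for (i in sel) tf[i, c_i, , ] <- (raw[[i]][c_i, , ] - mu) / sd_pop
      }
    }
  }
  labels <- vapply(epochs, function(e) ifelse(is.na(e$label), NA_character_, e$label),
                   character(1))
  list(tf = tf,
       labels = factor(labels, levels = stage_levels()),
       subjects = subjects,
       config = cfg)
}
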