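#' Stage-conditioned signal signatures for the synthetic generator
#'
#' Defines, per stage and channel, the oscillatory components (band-limited
#' noise given as center frequency, bandwidth and amplitude in microvolts),
#' transient events (kind, expected count per epoch, duration, amplitude)
#' and broadband noise level that the generator draws from. Channels are, in
#' order: frontal EEG (Fpz-Cz-like), parieto-occipital EEG (Pz-Oz-like), and
#' horizontal EOG.
#'
#' Defaults encode the classic stage signatures: alpha (8-12 Hz) with
#' frequent eye movements in W; theta (4-7 Hz) with slow eye movements in
#' N1; theta background plus 12-14 Hz spindle bursts and K-complexes in N2;
#' high-amplitude 0.5-2 Hz slow waves in N3; low-amplitude mixed-frequency
#' EEG with rapid saccades in REM.
#'
#' @param noise_sd Broadband Gaussian noise level in microvolts.
#' @param amp_jitter_sd Log-normal sd of the per-subject amplitude
#'   multiplier.
#' @param freq_jitter_sd Gaussian sd (Hz) of per-subject center-frequency
#'   jitter.
#' @return An object of class `stage_signature_config`.
#' @export
stage_signature_config <- function(noise_sd = 10, amp_jitter_sd = 0.1,
                                   freq_jitter_sd = 0.3) {
  osc <- function(center, bw, amp) list(center = center, bw = bw, amp = amp)
  ev <- function(kind, rate, dur, amp) list(kind = kind, rate = rate,
                                            dur = dur, amp = amp)
  sig <- list(
    W = list(
      eeg_frontal = list(osc = list(osc(10, 4, 30)), events = list()),
      eeg_posterior = list(osc = list(osc(10, 4, 40)), events = list()),
      eog = list(osc = list(osc(10, 4, 10)),
                 events = list(ev("saccade", 4, 0.4, 80)))),
    N1 = list(
      eeg_frontal = list(osc = list(osc(5.5, 3, 25)), events = list()),
      eeg_posterior = list(osc = list(osc(5.5, 3, 25)), events = list()),
      eog = list(osc = list(osc(1, 1, 10)),
                 events = list(ev("sem", 2, 2, 60)))),
    N2 = list(
      eeg_frontal = list(osc = list(osc(5.5, 3, 20)),
                         events = list(ev("spindle", 3, 1.0, 40),
                                       ev("kcomplex", 1.5, 0.8, 100))),
      eeg_posterior = list(osc = list(osc(5.5, 3, 20)),
                           events = list(ev("spindle", 3, 1.0, 30),
                                         ev("kcomplex", 1.5, 0.8, 80))),
      eog = list(osc = list(osc(1, 1, 8)), events = list())),
    N3 = list(
      eeg_frontal = list(osc = list(osc(1.25, 1.5, 90)), events = list()),
      eeg_posterior = list(osc = list(osc(1.25, 1.5, 75)), events = list()),
      eog = list(osc = list(osc(1, 1, 15)), events = list())),
    REM = list(
      eeg_frontal = list(osc = list(osc(5.5, 3, 15), osc(20, 10, 8)),
                         events = list()),
      eeg_posterior = list(osc = list(osc(5.5, 3, 15), osc(20, 10, 8)),
                           events = list()),
      eog = list(osc = list(osc(1, 1, 8)),
                 events = list(ev("saccade", 6, 0.3, 100))))
  )
  structure(list(stages = sig, noise_sd = noise_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 freq_jitter_sd = freq_jitter_sd,
                 channel_roles = c("eeg_frontal", "eeg_posterior", "eog")),
            class = "stage_signature_config")
}

# band-limited Gaussian noise with target standard deviation amp/2;
# 2nd-order Butterworth bandpass applied forward-backward (zero phase)
narrowband_noise <- function(n, fs, center, bw, amp) {
  lo <- max(center - bw / 2, 0.1)
  hi <- min(center + bw / 2, fs / 2 - 0.5)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2 * fs))
  x <- x[fs + seq_len(n)]                  # discard filter warm-up edges
  x * (amp / 2) / max(stats::sd(x), 1e-12)
}

# transient waveform templates, `n` samples long, peak amplitude `amp`
event_waveform <- function(kind, n, fs, amp) {
  t <- seq(0, 1, length.out = n)
  switch(kind,
    spindle = amp * sin(2 * pi * 13 * seq_len(n) / fs) *
      (0.5 - 0.5 * cos(2 * pi * t)),
    kcomplex = {                            # sharp negative then slow positive
      z <- (t - 0.35) / 0.12
      w <- -exp(-z^2 / 2) + 0.7 * exp(-((t - 0.65) / 0.2)^2 / 2)
      amp * w / max(abs(w))
    },
    saccade = {                             # rapid step up, hold, step back
      ramp <- pmin(1, pmax(0, (t - 0.05) / 0.1)) * pmin(1, pmax(0, (0.95 - t) / 0.1))
      amp * ramp * sample(c(-1, 1), 1)
    },
    sem = amp * sin(pi * t) * sample(c(-1, 1), 1),   # slow half-sine drift
    abort(paste0("unknown event kind: ", kind)))
}

# place Poisson-many events of one kind, rejecting starts that would
# truncate the waveform at the epoch borders
place_events <- function(x, fs, ev) {
  n <- length(x)
  dur_n <- round(ev$dur * fs)
  if (dur_n >= n) abort("event duration exceeds epoch length")
  count <- rpois(1, ev$rate)
  for (i in seq_len(count)) {
    start <- sample.int(n - dur_n, 1)
    x[start:(start + dur_n - 1L)] <-
      x[start:(start + dur_n - 1L)] + event_waveform(ev$kind, dur_n, fs, ev$amp)
  }
  x
}

#' Generate one synthetic stage-conditioned epoch
#'
#' Sums band-limited oscillations (randomized phase via fresh noise draws),
#' Poisson-placed transients, and broadband Gaussian noise, per channel.
#'
#' @param stage Stage label in `stage_levels()`.
#' @param cfg A [stage_signature_config()].
#' @param subject_jitter Optional list with `amp` (multiplier) and `freq`
#'   (Hz offset) applied to every component, as produced within
#'   [generate_dataset()].
#' @param sampling_rate Hz (default 100); the epoch has 30 s of samples.
#' @param subject_id,epoch_index Metadata passed to [epoch_record()].
#' @param seed Optional seed for a reproducible single epoch.
#' @return An [epoch_record()] with 3 channels.
#' @export
generate_epoch <- function(stage, cfg = stage_signature_config(),
                           subject_jitter = NULL, sampling_rate = 100,
                           subject_id = "SYN01", epoch_index = 0L,
                           seed = NULL) {
  if (!stage %in% stage_levels()) abort(paste0("invalid stage: ", stage))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(subject_jitter)) subject_jitter <- list(amp = 1, freq = 0)
  fs <- sampling_rate
  n <- fs * 30
  roles <- cfg$channel_roles
  signals <- matrix(0, length(roles), n)
  for (c_i in seq_along(roles)) {
    spec <- cfg$stages[[stage]][[roles[c_i]]]
    x <- rnorm(n, sd = cfg$noise_sd)
    for (o in spec$osc) {
      x <- x + narrowband_noise(n, fs, o$center + subject_jitter$freq, o$bw,
                                o$amp * subject_jitter$amp)
    }
    for (e in spec$events) {
      e$amp <- e$amp * subject_jitter$amp
      x <- place_events(x, fs, e)
    }
    signals[c_i, ] <- x
  }
  epoch_record(signals, sampling_rate = fs, label = stage,
               subject_id = subject_id, epoch_index = epoch_index)
}

# exact label quotas: floor allocation, remainder to largest fractional parts
quota_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1L
  }
  as.integer(counts)
}

#' Generate a synthetic multi-subject dataset
#'
#' Stage labels follow the target proportions by exact quota allocation,
#' epochs are divided evenly across synthetic subjects, and every subject
#' gets its own random amplitude/frequency jitter so that subject-wise
#' splits are meaningful. Identical seeds give bit-identical datasets.
#'
#' @param n_epochs Total number of epochs.
#' @param n_subjects Number of synthetic subjects (ids `SYN01`, `SYN02`, ...).
#' @param stage_proportions Named or ordered numeric vector of length 5
#'   summing to 1 (order W, N1, N2, N3, REM).
#' @param cfg A [stage_signature_config()].
#' @param seed Integer seed.
#' @return An object of class `psg_dataset`: list of `epochs`
#'   ([epoch_record()]s), a `manifest` tibble (epoch_index, subject_id,
#'   stage), `cfg` and `seed`.
#' @export
generate_dataset <- function(n_epochs, n_subjects = 1,
                             stage_proportions = rep(0.2, 5),
                             cfg = stage_signature_config(), seed = 1L) {
  if (n_subjects < 1) abort("need at least one subject")
  if (length(stage_proportions) != 5 || any(stage_proportions < 0) ||
      abs(sum(stage_proportions) - 1) > 1e-8) {
    abort("stage_proportions must be 5 nonnegative values summing to 1")
  }
  set.seed(seed)
  labels <- sample(rep(stage_levels(), times = quota_counts(n_epochs, stage_proportions)))
  subjects <- sprintf("SYN%02d", rep_len(seq_len(n_subjects), n_epochs))
  jitters <- lapply(seq_len(n_subjects), function(i) {
    list(amp = exp(rnorm(1, 0, cfg$amp_jitter_sd)),
         freq = rnorm(1, 0, cfg$freq_jitter_sd))
  })
  epochs <- vector("list", n_epochs)
  for (i in seq_len(n_epochs)) {
    sub <- rep_len(seq_len(n_subjects), n_epochs)[i]
    epochs[[i]] <- generate_epoch(labels[i], cfg,
                                  subject_jitter = jitters[[sub]],
                                  subject_id = subjects[i],
                                  epoch_index = i - 1L)
  }
  structure(
    list(epochs = epochs,
         manifest = tibble::tibble(epoch_index = seq_len(n_epochs) - 1L,
                                   subject_id = subjects,
                                   stage = factor(labels, levels = stage_levels())),
         cfg = cfg, seed = as.integer(seed)),
    class = "psg_dataset")
}

#' @export
print.psg_dataset <- function(x, ...) {
  cat(sprintf("<psg_dataset> %d epochs, %d subject(s), seed %d\n",
              length(x$epochs), length(unique(x$manifest$subject_id)), x$seed))
  print(table(x$manifest$stage))
  invisible(x)
}
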