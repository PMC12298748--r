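#' Default R&K to five-class label map
#'
#' Maps the eight Rechtschaffen-Kales scoring codes to the modern 5-class
#' scheme: S3 and S4 merge into N3; MOVEMENT and UNKNOWN epochs are marked
#' `EXCLUDE` and dropped by the loaders.
#'
#' @return Named character vector from R&K code to stage (or `"EXCLUDE"`).
#' @export
rk_label_map <- function() {
  c(W = "W", S1 = "N1", S2 = "N2", S3 = "N3", S4 = "N3",
    REM = "REM", MOVEMENT = "EXCLUDE", UNKNOWN = "EXCLUDE")
}

#' Map R&K codes through a label map
#'
#' @param codes Character vector of R&K codes.
#' @param map A label map as from [rk_label_map()]; must cover all codes.
#' @return Character vector of stages / `"EXCLUDE"`.
#' @export
map_rk_labels <- function(codes, map = rk_label_map()) {
  codes <- as.character(codes)
  bad <- setdiff(unique(codes), names(map))
  if (length(bad) > 0) {
    abort(paste0("unmapped R&K code(s): ", paste(bad, collapse = ", ")))
  }
  unname(map[codes])
}

# annotation text (EDF+ hypnogram convention) -> R&K code
annotation_to_rk <- function(text) {
  lut <- c("Sleep stage W" = "W", "Sleep stage 1" = "S1",
           "Sleep stage 2" = "S2", "Sleep stage 3" = "S3",
           "Sleep stage 4" = "S4", "Sleep stage R" = "REM",
           "Movement time" = "MOVEMENT", "Sleep stage ?" = "UNKNOWN")
  out <- lut[text]
  direct <- text %in% names(rk_label_map())
  out[direct] <- text[direct]
  if (anyNA(out)) {
    abort(paste0("unrecognized annotation(s): ",
                 paste(unique(text[is.na(out)]), collapse = "; ")))
  }
  unname(out)
}

rk_from_stage <- function(stage) {
  c(W = "Sleep stage W", N1 = "Sleep stage 1", N2 = "Sleep stage 2",
    N3 = "Sleep stage 3", REM = "Sleep stage R")[stage]
}

# ---- low-level EDF --------------------------------------------------------

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

write_edf_file <- function(path, signals, fs, labels_per_epoch, channel_labels,
                           phys_range = c(-500, 500),
                           annotation_texts = NULL) {
  n_sig <- nrow(signals)
  epoch_s <- 30L
  spr <- fs * epoch_s                     # samples per record per data signal
  n_rec <- ncol(signals) %/% spr
  ann_spr <- 60L                          # 120 bytes of annotation per record
  con <- file(path, "wb")
  on.exit(close(con))
  ns <- n_sig + 1L                        # + annotation signal
  header_bytes <- 256L * (1L + ns)
  writeChar(paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate 01-JAN-2000 X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(header_bytes, 8), pad_field("EDF+C", 44),
    pad_field(n_rec, 8), pad_field(epoch_s, 8), pad_field(ns, 4)),
    con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(c(channel_labels, "EDF Annotations"), 16)
  field(rep("", ns), 80)                                  # transducer
  field(c(rep("uV", n_sig), ""), 8)                       # physical dimension
  field(c(rep(phys_range[1], n_sig), -1), 8)
  field(c(rep(phys_range[2], n_sig), 1), 8)
  field(rep(-32768, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80)                                  # prefiltering
  field(c(rep(spr, n_sig), ann_spr), 8)
  field(rep("", ns), 32)
  scale <- (phys_range[2] - phys_range[1]) / 65535
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (s in seq_len(n_sig)) {
      phys <- pmin(pmax(signals[s, cols], phys_range[1]), phys_range[2])
      dig <- as.integer(round((phys - phys_range[1]) / scale) - 32768L)
      writeBin(dig, con, size = 2L, endian = "little")
    }
    onset <- (r - 1L) * epoch_s
    raw_tal <- c(charToRaw(paste0("+", onset, "\x14\x14")), as.raw(0))
    text <- if (!is.null(annotation_texts)) {
      annotation_texts[r]
    } else if (!is.null(labels_per_epoch) && !is.na(labels_per_epoch[r])) {
      rk_from_stage(labels_per_epoch[r])
    } else NA_character_
    if (!is.na(text)) {
      stage_tal <- paste0("+", onset, "\x15", epoch_s, "\x14", text, "\x14")
      raw_tal <- c(raw_tal, charToRaw(stage_tal), as.raw(0))
    }
    raw_tal <- c(raw_tal, raw(2L * ann_spr - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- per(16); transducer <- per(80); phys_dim <- per(8)
  phys_min <- as.numeric(per(8)); phys_max <- as.numeric(per(8))
  dig_min <- as.numeric(per(8)); dig_max <- as.numeric(per(8))
  prefilter <- per(80); spr <- as.integer(per(8)); per(32)
  list(n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, spr = spr)
}

read_edf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  raw_per_rec <- sum(h$spr) * 2L
  chunks <- lapply(seq_len(h$ns), function(s) vector("list", h$n_rec))
  for (r in seq_len(h$n_rec)) {
    rec <- readBin(con, "raw", raw_per_rec)
    if (length(rec) < raw_per_rec) abort("truncated EDF data record")
    at <- 0L
    for (s in seq_len(h$ns)) {
      nb <- h$spr[s] * 2L
      chunks[[s]][[r]] <- rec[at + seq_len(nb)]
      at <- at + nb
    }
  }
  signals <- list()
  annotations <- NULL
  for (s in seq_len(h$ns)) {
    all_raw <- do.call(c, chunks[[s]])
    if (h$labels[s] == "EDF Annotations") {
      annotations <- parse_tal_stream(chunks[[s]])
    } else {
      dig <- readBin(all_raw, "integer", n = length(all_raw) %/% 2L,
                     size = 2L, signed = TRUE, endian = "little")
      scale <- (h$phys_max[s] - h$phys_min[s]) / (h$dig_max[s] - h$dig_min[s])
      signals[[h$labels[s]]] <- h$phys_min[s] + (dig - h$dig_min[s]) * scale
    }
  }
  fs <- h$spr[h$labels != "EDF Annotations"] / h$rec_dur
  list(header = h, signals = signals,
       sampling_rates = setNames(fs, h$labels[h$labels != "EDF Annotations"]),
       annotations = annotations)
}

# parse EDF+ time-stamped annotation lists across records into a tibble of
# (onset_s, duration_s, text); TALs are NUL-delimited, fields by \x14,
# onset and duration by \x15. Bare record-timestamp TALs carry no text.
parse_tal_stream <- function(record_chunks) {
  out <- list()
  for (rec in record_chunks) {
    # split the raw record on NUL bytes into individual TALs
    breaks <- which(rec == as.raw(0))
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks - 1L, length(rec))
    for (seg in seq_along(starts)) {
      if (starts[seg] > ends[seg]) next
      tal <- rawToChar(rec[starts[seg]:ends[seg]])
      fields <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
      if (length(fields) < 2 || !grepl("^[+-][0-9.]+", fields[1])) next
      parts <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
      onset <- as.numeric(parts[1])
      dur <- if (length(parts) > 1) as.numeric(parts[2]) else NA_real_
      for (text in fields[-1]) {
        if (!nzchar(text)) next
        out[[length(out) + 1]] <- tibble::tibble(
          onset_s = onset, duration_s = dur, text = text)
      }
    }
  }
  if (length(out) == 0) return(tibble::tibble(onset_s = numeric(0),
                                              duration_s = numeric(0),
                                              text = character(0)))
  dplyr::bind_rows(out)
}

# ---- user-facing IO -------------------------------------------------------

#' Write a synthetic dataset to EDF files
#'
#' One EDF+ file per subject, holding the three signal channels plus a
#' hypnogram annotation track (one stage annotation per 30 s data record).
#' Signals are quantized to 16 bits over the given physical range.
#'
#' @param dataset A `psg_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param phys_range Physical range in microvolts for quantization.
#' @return Character vector of the written file paths (named by subject).
#' @export
write_edf <- function(dataset, dir, phys_range = c(-500, 500)) {
  if (!inherits(dataset, "psg_dataset") || length(dataset$epochs) == 0) {
    abort("empty or invalid dataset")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- unique(dataset$manifest$subject_id)
  paths <- character(0)
  for (sub in subjects) {
    idx <- which(dataset$manifest$subject_id == sub)
    idx <- idx[order(dataset$manifest$epoch_index[idx])]
    eps <- dataset$epochs[idx]
    signals <- do.call(cbind, lapply(eps, function(e) e$signals))
    labels <- as.character(dataset$manifest$stage[idx])
    path <- file.path(dir, paste0(sub, ".edf"))
    write_edf_file(path, signals, eps[[1]]$sampling_rate, labels,
                   c("EEG Fpz-Cz", "EEG Pz-Oz", "EOG horizontal")[seq_len(nrow(signals))],
                   phys_range)
    paths[sub] <- path
  }
  paths
}

#' Load an EDF polysomnography recording as labeled epochs
#'
#' Reads the signal channels, aligns hypnogram annotations to 30 s epochs,
#' maps R&K codes to the 5-class scheme (S3/S4 -> N3), drops MOVEMENT and
#' UNKNOWN epochs, and derives the subject id from the file name
#' (Sleep-EDF-style: the first five characters of the stem, falling back to
#' the full stem).
#'
#' @param psg_path EDF file with the signals.
#' @param hypnogram_path Optional separate EDF file carrying the annotation
#'   track; defaults to annotations embedded in `psg_path`.
#' @param channel_names Channels to keep, in order; `NULL` keeps all.
#' @param label_map Label map as from [rk_label_map()].
#' @param target_rate Required sampling rate (Hz); channels at other rates
#'   are polyphase-resampled with a warning.
#' @return A `psg_dataset` (epochs + manifest), unscored epochs excluded.
#' @export
load_recording <- function(psg_path, hypnogram_path = NULL,
                           channel_names = NULL, label_map = rk_label_map(),
                           target_rate = 100) {
  if (!file.exists(psg_path)) abort(paste0("no such file: ", psg_path))
  edf <- read_edf_file(psg_path)
  ann <- edf$annotations
  if (!is.null(hypnogram_path)) {
    ann <- read_edf_file(hypnogram_path)$annotations
  }
  if (is.null(ann) || nrow(ann) == 0) abort("no hypnogram annotations found")
  available <- names(edf$signals)
  if (is.null(channel_names)) channel_names <- available
  missing <- setdiff(channel_names, available)
  if (length(missing) > 0) {
    abort(sprintf("channel(s) not found: %s; available: %s",
                  paste(missing, collapse = ", "),
                  paste(available, collapse = ", ")))
  }
  sigs <- lapply(channel_names, function(ch) {
    x <- edf$signals[[ch]]
    fs <- edf$sampling_rates[[ch]]
    if (fs != target_rate) {
      warn(sprintf("resampling channel %s from %g Hz to %g Hz", ch, fs, target_rate))
      x <- as.numeric(signal::resample(x, target_rate, fs))
    }
    x
  })
  n_samp <- min(lengths(sigs))
  spe <- target_rate * 30L
  n_epochs <- n_samp %/% spe
  # stage lookup per epoch onset from (possibly long-duration) annotations
  stages <- ann[grepl("stage|Movement|^[WSRMU]", ann$text), , drop = FALSE]
  rk <- annotation_to_rk(stages$text)
  mapped <- map_rk_labels(rk, label_map)
  ends <- ifelse(is.na(stages$duration_s), stages$onset_s + 30,
                 stages$onset_s + stages$duration_s)
  subject <- edf_subject_id(psg_path)
  epochs <- list()
  rows <- list()
  for (i in seq_len(n_epochs)) {
    onset <- (i - 1) * 30
    hit <- which(stages$onset_s <= onset & ends > onset)
    if (length(hit) == 0) next
    lab <- mapped[hit[length(hit)]]
    if (lab == "EXCLUDE") next
    m <- do.call(rbind, lapply(sigs, function(x) x[(i - 1L) * spe + seq_len(spe)]))
    k <- length(epochs) + 1L
    epochs[[k]] <- epoch_record(m, sampling_rate = target_rate, label = lab,
                                subject_id = subject, epoch_index = i - 1L)
    rows[[k]] <- tibble::tibble(epoch_index = i - 1L, subject_id = subject,
                                stage = lab)
  }
  if (length(epochs) == 0) abort("no scorable epochs in recording")
  manifest <- dplyr::bind_rows(rows)
  manifest$stage <- factor(manifest$stage, levels = stage_levels())
  structure(list(epochs = epochs, manifest = manifest, cfg = NULL, seed = NA_integer_),
            class = "psg_dataset")
}

edf_subject_id <- function(path) {
  stem <- sub("\\.[^.]*$", "", basename(path))
  if (nchar(stem) >= 5) substr(stem, 1, 5) else stem
}

#' Restrict a labeled recording to the in-bed window
#'
#' Keeps epochs from 30 min (by default) before the first non-wake epoch
#' through 30 min after the last non-wake epoch, clipped to the recording
#' bounds; this trims the long lights-on wake periods at either end.
#'
#' @param dataset A `psg_dataset` with labeled epochs.
#' @param before_after_minutes Margin on each side of the sleep period.
#' @return The filtered `psg_dataset`; an all-wake recording is returned
#'   unchanged with a warning.
#' @export
trim_to_in_bed <- function(dataset, before_after_minutes = 30) {
  stages <- as.character(dataset$manifest$stage)
  sleep <- which(stages != "W")
  if (length(sleep) == 0) {
    warn("recording contains no sleep epochs; returning unchanged")
    return(dataset)
  }
  margin <- as.integer(round(before_after_minutes * 60 / 30))
  keep <- max(1L, min(sleep) - margin):min(length(stages), max(sleep) + margin)
  dataset$epochs <- dataset$epochs[keep]
  dataset$manifest <- dataset$manifest[keep, , drop = FALSE]
  dataset
}
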