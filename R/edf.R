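# Minimal European Data Format (EDF) support: enough of the fixed-layout
# header and 16-bit sample records to import a synchronized EEG-EMG trial
# whose sampling rates come from the file header, and to write synthetic
# fixtures. Not a general EDF+ implementation (no annotations,
# discontinuous records, or sub-second record durations other than what the
# header states).

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

# format a number into <= 8 ASCII chars (EDF physical min/max fields)
edf_num8 <- function(x) {
  vapply(x, function(v) {
    for (digits in 7:1) {
      s <- sprintf("%.*g", digits, v)
      if (nchar(s) <= 8L) return(s)
    }
    stop("cannot format ", v, " into 8 characters")
  }, character(1))
}

#' Write a trial as an EDF file
#'
#' Serializes a [trial_recording()] to EDF: one data record per second, EEG
#' and EMG signals side by side with their native samples-per-record, 16-bit
#' samples scaled to each channel's physical range. EDF quantizes to 16
#' bits, so the round trip is approximate (relative error about 2^-15 of
#' the channel range). Intended for building synthetic EDF fixtures and for
#' interoperability, not as the package's lossless container (see
#' [write_dataset()]).
#'
#' @param trial A [trial_recording()] whose duration is a whole number of
#'   seconds.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(trial, path) {
  dur <- trial_duration(trial)
  if (abs(dur - round(dur)) > 1e-9) stop("EDF writer needs a whole-second duration")
  n_rec <- as.integer(round(dur))
  sig <- c(lapply(seq_len(nrow(trial$eeg)), function(i) trial$eeg[i, ]),
           lapply(seq_len(nrow(trial$emg)), function(i) trial$emg[i, ]))
  ns <- length(sig)
  spr <- c(rep(trial$eeg_rate, nrow(trial$eeg)), rep(trial$emg_rate, nrow(trial$emg)))
  labels <- c(rownames(trial$eeg), rownames(trial$emg))
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  phys_min <- vapply(sig, min, numeric(1))
  phys_max <- vapply(sig, max, numeric(1))
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  # scale against the values as printed in the 8-char header fields, so the
  # reader reconstructs with the same range
  phys_min <- as.numeric(edf_num8(phys_min))
  phys_max <- pmax(as.numeric(edf_num8(phys_max)), phys_min + 1e-6)
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8L),
    edf_pad(paste("subject", trial$subject_id), 80L),
    edf_pad(paste("recording", trial$movement, trial$group), 80L),
    "01.01.26", "00.00.00",
    edf_pad(256L * (1L + ns), 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad(1L, 8L),
    edf_pad(ns, 4L))
  writeChar(header, con, nchars = nchar(header), eos = NULL)
  fields <- list(
    edf_pad(labels, 16L), edf_pad("", 80L)[rep(1L, ns)], edf_pad("uV", 8L)[rep(1L, ns)],
    edf_pad(edf_num8(phys_min), 8L), edf_pad(edf_num8(phys_max), 8L),
    edf_pad(dig_min, 8L)[rep(1L, ns)], edf_pad(dig_max, 8L)[rep(1L, ns)],
    edf_pad("", 80L)[rep(1L, ns)], edf_pad(spr, 8L), edf_pad("", 32L)[rep(1L, ns)])
  for (f in fields) {
    s <- paste(f, collapse = "")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      cols <- (r - 1L) * spr[i] + seq_len(spr[i])
      dig <- round((sig[[i]][cols] - phys_min[i]) * scale[i]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the EDF header and sample records into per-signal numeric vectors
#' with physical scaling applied. Sampling rates are taken from the header
#' (samples per record / record duration).
#'
#' @param path EDF file.
#' @return A list with `labels`, `rates` (Hz), `signals` (named list of
#'   numeric vectors), `n_records`, and `record_duration` (s).
#' @export
read_edf <- function(path) {
  if (!file.exists(path) || file.size(path) < 256)
    stop("not a valid EDF file (shorter than one header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) != 1L || nchar(s, type = "bytes") < n)
      stop("not a valid EDF file (truncated header): ", path)
    s
  }
  version <- trimws(rd(8L))
  rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- suppressWarnings(as.integer(trimws(rd(8L))))
  rd(44L)
  n_rec <- suppressWarnings(as.integer(trimws(rd(8L))))
  rec_dur <- suppressWarnings(as.numeric(trimws(rd(8L))))
  ns <- suppressWarnings(as.integer(trimws(rd(4L))))
  if (anyNA(c(ns, n_rec, rec_dur)) || ns < 1L || n_rec < 1L || rec_dur <= 0)
    stop("not a valid EDF header: ", path)
  field <- function(width) trimws(vapply(seq_len(ns), function(i) rd(width), character(1)))
  labels <- field(16L)
  field(80L); field(8L)
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)
  spr <- as.integer(field(8L))
  field(32L)
  if (isTRUE(header_bytes != 256L * (1L + ns)))
    stop("EDF header size field inconsistent in ", path)
  signals <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i]) stop("EDF file truncated: ", path)
      phys <- phys_min[i] + (dig - dig_min[i]) *
        (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      signals[[i]][(r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  names(signals) <- labels
  list(labels = labels, rates = spr / rec_dur, signals = signals,
       n_records = n_rec, record_duration = rec_dur)
}

#' Import an EDF file as a trial
#'
#' Splits the EDF's signals into EEG and EMG blocks (the first `n_eeg`
#' signals are EEG, the rest EMG — the package's fixed channel order) and
#' builds a [trial_recording()] with rates read from the EDF header. EDF
#' carries no movement/group labels, so these are supplied by the caller.
#'
#' @param path EDF file.
#' @param movement,subject_id,group Trial metadata.
#' @param n_eeg Number of leading EEG signals (default 32).
#' @return A [trial_recording()].
#' @export
read_edf_trial <- function(path, movement, subject_id = "edf", group = "healthy",
                           n_eeg = 32L) {
  edf <- read_edf(path)
  ns <- length(edf$signals)
  if (ns <= n_eeg) stop("EDF has ", ns, " signals; need more than n_eeg = ", n_eeg)
  eeg_rates <- unique(edf$rates[seq_len(n_eeg)])
  emg_rates <- unique(edf$rates[(n_eeg + 1L):ns])
  if (length(eeg_rates) != 1L || length(emg_rates) != 1L)
    stop("mixed sampling rates within a modality block in ", path)
  eeg <- do.call(rbind, edf$signals[seq_len(n_eeg)])
  emg <- do.call(rbind, edf$signals[(n_eeg + 1L):ns])
  rownames(eeg) <- edf$labels[seq_len(n_eeg)]
  rownames(emg) <- edf$labels[(n_eeg + 1L):ns]
  trial_recording(eeg, emg, movement, subject_id, group,
                  eeg_rate = eeg_rates, emg_rate = emg_rates)
}
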