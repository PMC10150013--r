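#' Standard channel names
#'
#' 32 EEG electrodes in 10-10 montage order followed by the 8 forearm/arm
#' EMG sites: flexor digitorum superficialis (FDS), flexor carpi ulnaris
#' (FCU), flexor carpi radialis (FCR), extensor carpi ulnaris (ECU),
#' extensor carpi radialis longus (ECRL), biceps brachii short head (BBS),
#' triceps brachii long head (TBL), lateral deltoid (LD).
#'
#' @format Character vectors.
#' @name channel_names
NULL

#' @rdname channel_names
#' @export
eeg_channel_names <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
  "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6", "P7", "P3",
  "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10", "TP9", "TP10"
)

#' @rdname channel_names
#' @export
emg_channel_names <- c("FDS", "FCU", "FCR", "ECU", "ECRL", "BBS", "TBL", "LD")

movement_levels <- c("push", "pull")
group_levels <- c("healthy", "patient")

#' Construct a synchronized EEG-EMG trial
#'
#' One trial of simultaneously recorded EEG and EMG covering the same time
#' span (3 s by default acquisition settings: 32 EEG channels at 500 Hz and
#' 8 EMG channels at 1000 Hz), with its movement label and subject
#' metadata.
#'
#' @param eeg Channels-by-samples numeric matrix (microvolt scale).
#' @param emg Channels-by-samples numeric matrix.
#' @param movement `"push"` or `"pull"`.
#' @param subject_id Subject identifier string.
#' @param group `"healthy"` or `"patient"`.
#' @param eeg_rate,emg_rate Sampling rates in Hz.
#' @param trial_id Optional identifier; defaults to `""` until assigned by a
#'   dataset writer.
#' @return A `trial_recording` object.
#' @export
trial_recording <- function(eeg, emg, movement, subject_id, group,
                            eeg_rate = 500, emg_rate = 1000, trial_id = "") {
  if (!is.matrix(eeg) || !is.numeric(eeg)) stop("eeg must be a numeric matrix")
  if (!is.matrix(emg) || !is.numeric(emg)) stop("emg must be a numeric matrix")
  if (anyNA(eeg) || any(!is.finite(eeg))) stop("eeg contains non-finite samples")
  if (anyNA(emg) || any(!is.finite(emg))) stop("emg contains non-finite samples")
  movement <- match.arg(movement, movement_levels)
  group <- match.arg(group, group_levels)
  dur_eeg <- ncol(eeg) / eeg_rate
  dur_emg <- ncol(emg) / emg_rate
  if (abs(dur_eeg - dur_emg) > 1e-9)
    stop(sprintf("EEG (%.3f s) and EMG (%.3f s) durations differ; trial is not synchronized",
                 dur_eeg, dur_emg))
  if (is.null(rownames(eeg)) && nrow(eeg) == length(eeg_channel_names))
    rownames(eeg) <- eeg_channel_names
  if (is.null(rownames(emg)) && nrow(emg) == length(emg_channel_names))
    rownames(emg) <- emg_channel_names
  structure(
    list(eeg = eeg, emg = emg, movement = movement,
         subject_id = as.character(subject_id), group = group,
         eeg_rate = as.numeric(eeg_rate), emg_rate = as.numeric(emg_rate),
         trial_id = as.character(trial_id)),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s | subject %s (%s)\n  EEG %d x %d @ %g Hz, EMG %d x %d @ %g Hz (%.1f s)\n",
    x$movement, x$subject_id, x$group,
    nrow(x$eeg), ncol(x$eeg), x$eeg_rate,
    nrow(x$emg), ncol(x$emg), x$emg_rate, ncol(x$eeg) / x$eeg_rate))
  invisible(x)
}

trial_duration <- function(trial) ncol(trial$eeg) / trial$eeg_rate

#' Construct a segment window
#'
#' One 0.5 s multichannel analysis window cut from a preprocessed trial:
#' 40 rows (32 EEG then 8 EMG, fixed order) by 250 samples at 500 Hz, with
#' its sub-action label `(movement, position)`.
#'
#' @param data Channels-by-samples numeric matrix.
#' @param movement `"push"` or `"pull"`.
#' @param position Integer segment index in 0..5.
#' @param subject_id,group Copied trial metadata.
#' @param trial_id Identifier of the source trial.
#' @param rate Sampling rate in Hz.
#' @param n_positions Number of segments per trial (default 6).
#' @return A `segment_window` object.
#' @export
segment_window <- function(data, movement, position, subject_id, group,
                           trial_id = "", rate = 500, n_positions = 6L) {
  movement <- match.arg(movement, movement_levels)
  position <- as.integer(position)
  if (is.na(position) || position < 0L || position >= n_positions)
    stop(sprintf("position must be in 0..%d", n_positions - 1L))
  structure(
    list(data = data, movement = movement, position = position,
         subject_id = as.character(subject_id), group = group,
         trial_id = as.character(trial_id), rate = as.numeric(rate),
         n_positions = as.integer(n_positions)),
    class = "segment_window"
  )
}

#' @export
print.segment_window <- function(x, ...) {
  cat(sprintf("<segment_window> %s position %d | %d x %d @ %g Hz | subject %s\n",
              x$movement, x$position, nrow(x$data), ncol(x$data), x$rate,
              x$subject_id))
  invisible(x)
}
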