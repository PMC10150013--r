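#' @importFrom signal fir1
NULL

# Zero-phase FIR application: the kernel h is symmetric (linear phase), so a
# single convolution with the group delay removed is exactly zero-phase.
# Edges are reflection-padded to avoid the start-up transient that plain
# filtering leaves on short epochs. FFT convolution keeps long kernels cheap.
apply_fir_zerophase <- function(x, h) {
  n <- length(x)
  m <- length(h)
  half <- (m - 1L) %/% 2L
  pad <- min(n - 1L, m)
  left <- 2 * x[1L] - x[(pad + 1L):2L]   # odd reflection about the endpoints
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  nf <- stats::nextn(length(xp) + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nf - length(xp)))) *
                     stats::fft(c(h, numeric(nf - m))), inverse = TRUE)) / nf
  y[(pad + half) + seq_len(n)]
}

filter_rows <- function(mat, h) {
  out <- mat
  for (i in seq_len(nrow(mat))) out[i, ] <- apply_fir_zerophase(mat[i, ], h)
  out
}

# FIR kernel design via signal::fir1 (Hamming window). Orders give a ~3 Hz
# transition band at the respective rates, ample for >= 20 dB stop-band
# attenuation one transition-width past the edge.
design_bandpass <- function(low, high, rate, taps = NULL) {
  nyq <- rate / 2
  if (low <= 0 || high >= nyq)
    stop(sprintf("band edges (%g, %g) Hz must lie strictly inside (0, Nyquist = %g) Hz",
                 low, high, nyq))
  if (is.null(taps)) taps <- 2L * floor(rate) + 1L
  signal::fir1(taps - 1L, c(low, high) / nyq, type = "pass")
}

design_lowpass <- function(cutoff, rate, taps = 101L) {
  nyq <- rate / 2
  if (cutoff >= nyq) stop("lowpass cutoff must be below Nyquist")
  signal::fir1(taps - 1L, cutoff / nyq, type = "low")
}

#' Downsample the EMG of a trial to the EEG rate
#'
#' Anti-alias lowpass filters (zero-phase FIR, cutoff 0.8 of the target
#' Nyquist) and decimates each EMG channel so both modalities share one
#' sampling rate. The decimation factor `emg_rate / target_rate` must be an
#' integer; the EEG is untouched.
#'
#' @param trial A [trial_recording()].
#' @param target_rate Target rate in Hz (default the trial's EEG rate).
#' @return The trial with EMG resampled and `emg_rate == target_rate`.
#' @export
resample_emg <- function(trial, target_rate = trial$eeg_rate) {
  factor <- trial$emg_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("EMG rate %g Hz is not an integer multiple of the target %g Hz",
                 trial$emg_rate, target_rate))
  factor <- as.integer(round(factor))
  if (factor == 1L) return(trial)
  h <- design_lowpass(0.8 * target_rate / 2, trial$emg_rate)
  keep <- seq(1L, ncol(trial$emg), by = factor)
  emg <- trial$emg
  out <- matrix(0, nrow(emg), length(keep), dimnames = list(rownames(emg), NULL))
  for (i in seq_len(nrow(emg)))
    out[i, ] <- apply_fir_zerophase(emg[i, ], h)[keep]
  trial$emg <- out
  trial$emg_rate <- target_rate
  trial
}

#' Band-pass filter a trial
#'
#' Zero-phase FIR band-pass filtering of both modalities: EEG 2-40 Hz and
#' EMG 2-100 Hz by default (the EMG band assumes the EMG is still at a rate
#' whose Nyquist exceeds the upper edge). Zero-phase application preserves
#' the timing of the sub-action structure.
#'
#' @param trial A [trial_recording()].
#' @param eeg_band,emg_band `c(low, high)` Hz.
#' @return The filtered trial.
#' @export
bandpass_trial <- function(trial, eeg_band = c(2, 40), emg_band = c(2, 100)) {
  h_eeg <- design_bandpass(eeg_band[1L], eeg_band[2L], trial$eeg_rate)
  h_emg <- design_bandpass(emg_band[1L], emg_band[2L], trial$emg_rate)
  trial$eeg <- filter_rows(trial$eeg, h_eeg)
  trial$emg <- filter_rows(trial$emg, h_emg)
  trial
}

#' Optional ICA artifact-removal hook
#'
#' Pass-through hook for an external independent component analysis
#' cleanup. The package does not implement ICA; supply `fun` to delegate to
#' one (it receives and must return the trial). Disabled (identity) by
#' default.
#'
#' @param trial A [trial_recording()].
#' @param fun `NULL` (default, no-op) or a `function(trial) -> trial`.
#' @return The (possibly cleaned) trial.
#' @export
ica_hook <- function(trial, fun = NULL) {
  if (is.null(fun)) return(trial)
  out <- fun(trial)
  if (!inherits(out, "trial_recording")) stop("ICA hook must return a trial_recording")
  out
}

#' Cut a preprocessed trial into sub-action segment windows
#'
#' Stacks the 32 EEG rows over the 8 EMG rows (fixed order) and partitions
#' the 3 s epoch into `n_segments` contiguous, non-overlapping windows of
#' equal length (six 0.5 s windows by default), labeling each with the
#' trial's movement and its position index 0..5.
#'
#' @param trial A trial whose EMG has been resampled to the EEG rate.
#' @param n_segments Number of segments (default 6).
#' @param duration Expected epoch duration in seconds (default 3).
#' @return List of `n_segments` [segment_window()] objects in time order.
#' @export
epoch_and_segment <- function(trial, n_segments = 6L, duration = 3) {
  if (trial$emg_rate != trial$eeg_rate)
    stop("EMG must be resampled to the EEG rate before segmentation (see resample_emg)")
  rate <- trial$eeg_rate
  need <- as.integer(round(duration * rate))
  if (ncol(trial$eeg) < need)
    stop(sprintf("trial too short: %d samples < %d (%g s at %g Hz)",
                 ncol(trial$eeg), need, duration, rate))
  stacked <- rbind(trial$eeg[, seq_len(need), drop = FALSE],
                   trial$emg[, seq_len(need), drop = FALSE])
  seg_len <- need %/% n_segments
  if (seg_len * n_segments != need)
    stop("epoch length is not divisible by the number of segments")
  lapply(seq_len(n_segments) - 1L, function(pos) {
    cols <- pos * seg_len + seq_len(seg_len)
    segment_window(stacked[, cols, drop = FALSE], trial$movement, pos,
                   trial$subject_id, trial$group, trial$trial_id, rate,
                   n_positions = as.integer(n_segments))
  })
}

#' Trial-level stratified train/test split
#'
#' Splits trials (never individual segments — all six windows of a trial
#' stay on one side, guarding against leakage) into train and test sets,
#' stratified by movement so class proportions differ by at most one trial
#' per class. Deterministic given the seed.
#'
#' @param trials List of [trial_recording()] objects.
#' @param ratio Train:test ratio as `c(train, test)` (default `c(4, 1)`).
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` lists of trials.
#' @export
split_train_test <- function(trials, ratio = c(4, 1), seed = 1L) {
  if (length(trials) < 2L) stop("need at least 2 trials to split")
  test_frac <- ratio[2L] / sum(ratio)
  movements <- vapply(trials, function(t) t$movement, character(1))
  test_idx <- integer(0)
  with_seed(seed, {
    for (mv in unique(movements)) {
      idx <- which(movements == mv)
      n_test <- round(length(idx) * test_frac)
      if (n_test > 0L)
        test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  if (length(test_idx) == 0L || length(test_idx) == length(trials))
    stop("split leaves one side empty; adjust ratio or add trials")
  list(train = trials[-sort(test_idx)], test = trials[sort(test_idx)])
}

#' Preprocess one trial end to end
#'
#' Resampling, band-pass filtering, the optional ICA hook, and
#' segmentation, in the standard order.
#'
#' @inheritParams resample_emg
#' @inheritParams bandpass_trial
#' @inheritParams epoch_and_segment
#' @param ica_fun Optional ICA delegate, see [ica_hook()].
#' @return List of [segment_window()] objects.
#' @export
preprocess_trial <- function(trial, eeg_band = c(2, 40), emg_band = c(2, 100),
                             n_segments = 6L, duration = 3, ica_fun = NULL) {
  trial <- resample_emg(trial)
  trial <- bandpass_trial(trial, eeg_band, emg_band)
  trial <- ica_hook(trial, ica_fun)
  epoch_and_segment(trial, n_segments, duration)
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
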