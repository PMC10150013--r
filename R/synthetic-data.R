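#' Generator profile for synthetic EEG-EMG trials
#'
#' Describes the statistical structure planted in synthetic trials: per-band,
#' per-segment, per-class EEG carrier amplitudes; a corticomuscular coupling
#' strength injecting a shared band-limited latent drive into selected EEG
#' and EMG channels; and the white-noise floor. The default profile is the
#' "easy" study condition: class- and segment-dependent alpha/beta ramps in
#' opposite directions for push vs pull, a constant theta offset between the
#' classes, and class-dependent coupled EMG sites, all well above the noise
#' floor so the planted structure is recoverable from short segments.
#'
#' @param band_weights 5 x 6 x 2 array (band x segment x class, classes
#'   ordered push, pull) of nonnegative carrier amplitudes. Default: alpha
#'   ramps 1 to 3 across segments for push and 3 to 1 for pull, beta the
#'   mirror image, theta 2.5 (push) vs 0.8 (pull), delta and low gamma 1.
#' @param coupling Nonnegative gain of the shared 15-30 Hz latent drive
#'   (default 1.5).
#' @param coupled_eeg EEG channel indices receiving the latent drive
#'   (default C3, C4).
#' @param coupled_emg_push,coupled_emg_pull EMG channel indices (1..8)
#'   receiving the drive for each movement (defaults FDS+FCU for push,
#'   ECU+ECRL for pull, echoing flexor/extensor roles).
#' @param noise_sd White-noise standard deviation added to every EEG
#'   channel, must be positive (default 0.5).
#' @param emg_noise_sd White-noise floor of the EMG channels (default 0.5).
#' @param emg_drive Amplitude of the broadband (20-100 Hz) EMG activity
#'   carrier (default 1).
#' @return A `generator_profile` object.
#' @export
generator_profile <- function(band_weights = default_band_weights(),
                              coupling = 1.5,
                              coupled_eeg = c(13L, 15L),
                              coupled_emg_push = c(1L, 2L),
                              coupled_emg_pull = c(4L, 5L),
                              noise_sd = 0.5, emg_noise_sd = 0.5,
                              emg_drive = 1) {
  if (!is.array(band_weights) || !all(dim(band_weights) == c(5L, 6L, 2L)))
    stop("band_weights must be a 5 x 6 x 2 array (band x segment x class)")
  if (any(band_weights < 0)) stop("band_weights must be nonnegative")
  if (!is.numeric(coupling) || coupling < 0) stop("coupling must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("invalid profile: noise_sd must be positive")
  if (!is.numeric(emg_noise_sd) || emg_noise_sd <= 0)
    stop("invalid profile: emg_noise_sd must be positive")
  if (identical(band_weights[, , 1L], band_weights[, , 2L]))
    warning("push and pull share identical band weights; planted class structure is absent")
  structure(
    list(band_weights = band_weights, coupling = coupling,
         coupled_eeg = as.integer(coupled_eeg),
         coupled_emg = list(push = as.integer(coupled_emg_push),
                            pull = as.integer(coupled_emg_pull)),
         noise_sd = noise_sd, emg_noise_sd = emg_noise_sd,
         emg_drive = emg_drive),
    class = "generator_profile"
  )
}

#' @rdname generator_profile
#' @export
default_band_weights <- function() {
  w <- array(1, dim = c(5L, 6L, 2L),
             dimnames = list(c("delta", "theta", "alpha", "beta", "low_gamma"),
                             NULL, c("push", "pull")))
  ramp_up <- 1 + 2 * (0:5) / 5   # 1 .. 3 across the six segments
  ramp_down <- rev(ramp_up)
  w["alpha", , "push"] <- ramp_up
  w["alpha", , "pull"] <- ramp_down
  w["beta", , "push"] <- ramp_down
  w["beta", , "pull"] <- ramp_up
  w["theta", , "push"] <- 2.5
  w["theta", , "pull"] <- 0.8
  w
}

#' Degraded profile emulating impaired motor control
#'
#' The default profile with the class/segment contrast attenuated (weight
#' deviations from baseline scaled by `contrast`), the noise floor raised
#' (`noise_mult`), and the corticomuscular coupling attenuated
#' (`coupling_mult`) — the direction of degradation expected in a patient
#' group, which lowers downstream movement scores.
#'
#' @param base Profile to degrade (default [generator_profile()]).
#' @param contrast Scale on weight deviations from 1 (default 0.4).
#' @param noise_mult Multiplier on both noise floors (default 3).
#' @param coupling_mult Multiplier on coupling (default 0.3).
#' @return A `generator_profile`.
#' @export
patient_profile <- function(base = generator_profile(), contrast = 0.4,
                            noise_mult = 3, coupling_mult = 0.3) {
  w <- 1 + contrast * (base$band_weights - 1)
  generator_profile(band_weights = w,
                    coupling = base$coupling * coupling_mult,
                    coupled_eeg = base$coupled_eeg,
                    coupled_emg_push = base$coupled_emg$push,
                    coupled_emg_pull = base$coupled_emg$pull,
                    noise_sd = base$noise_sd * noise_mult,
                    emg_noise_sd = base$emg_noise_sd * noise_mult,
                    emg_drive = base$emg_drive)
}

# band-limited unit-ish noise carrier: white noise through the band FIR
band_carrier <- function(n, band, rate) {
  h <- design_bandpass(band[1L], band[2L], rate,
                       taps = 2L * floor(rate / 2) + 1L)
  x <- apply_fir_zerophase(stats::rnorm(n), h)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

generator_bands <- list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 15),
                        beta = c(15, 30), low_gamma = c(30, 40))

#' Generate one synthetic EEG-EMG trial
#'
#' Simulates a 3 s synchronized trial (32 EEG channels at 500 Hz, 8 EMG
#' channels at 1000 Hz). Each EEG channel is a sum of five band-limited
#' Gaussian carriers whose per-segment amplitudes follow the profile's
#' class-dependent weights, plus white noise. EMG channels carry broadband
#' 20-100 Hz activity with a class-dependent temporal envelope plus white
#' noise. A shared 15-30 Hz latent series is injected into the profile's
#' coupled EEG channels and the movement's coupled EMG channels with a
#' segment-ramped gain, planting recoverable corticomuscular coupling.
#' Bit-identical output for identical `(movement, profile, seed)`.
#'
#' @param movement `"push"` or `"pull"`.
#' @param profile A [generator_profile()].
#' @param seed Integer seed.
#' @param subject_id,group Metadata for the trial.
#' @param duration Trial length in seconds (default 3).
#' @param eeg_rate,emg_rate Sampling rates in Hz (defaults 500 and 1000).
#' @return A [trial_recording()].
#' @export
generate_trial <- function(movement, profile = generator_profile(), seed = 1L,
                           subject_id = "sim01", group = "healthy",
                           duration = 3, eeg_rate = 500, emg_rate = 1000) {
  movement <- match.arg(movement, movement_levels)
  if (!inherits(profile, "generator_profile")) stop("profile must be a generator_profile")
  n_eeg_ch <- 32L
  n_emg_ch <- 8L
  n_seg <- 6L
  n_eeg <- as.integer(duration * eeg_rate)
  n_emg <- as.integer(duration * emg_rate)
  seg_len_eeg <- n_eeg %/% n_seg
  seg_len_emg <- n_emg %/% n_seg
  w <- profile$band_weights[, , movement]
  with_seed(seed, {
    # per-segment amplitude envelope at the EEG rate, one row per band
    env <- matrix(0, 5L, n_eeg)
    for (s in seq_len(n_seg))
      env[, (s - 1L) * seg_len_eeg + seq_len(seg_len_eeg)] <- w[, s]
    eeg <- matrix(stats::rnorm(n_eeg_ch * n_eeg, sd = profile$noise_sd),
                  n_eeg_ch, n_eeg)
    for (ch in seq_len(n_eeg_ch)) {
      for (b in seq_len(5L)) {
        eeg[ch, ] <- eeg[ch, ] +
          env[b, ] * band_carrier(n_eeg, generator_bands[[b]], eeg_rate)
      }
    }
    # EMG: broadband activity with a class-dependent temporal envelope
    ramp <- if (movement == "push") 0.5 + (0:5) / 5 * 1.5 else 2 - (0:5) / 5 * 1.5
    emg_env <- rep(ramp, each = seg_len_emg)
    emg <- matrix(stats::rnorm(n_emg_ch * n_emg, sd = profile$emg_noise_sd),
                  n_emg_ch, n_emg)
    for (ch in seq_len(n_emg_ch)) {
      emg[ch, ] <- emg[ch, ] +
        profile$emg_drive * emg_env * band_carrier(n_emg, c(20, 100), emg_rate)
    }
    # shared latent drive: 15-30 Hz at the EMG rate; the EEG copy is its
    # decimated version (band is far below the EEG Nyquist)
    if (profile$coupling > 0) {
      latent <- band_carrier(n_emg, c(15, 30), emg_rate)
      latent_eeg <- latent[seq(1L, n_emg, by = as.integer(emg_rate / eeg_rate))]
      gain <- profile$coupling * rep(0.5 + (0:5) / 5, each = seg_len_emg)
      gain_eeg <- profile$coupling * rep(0.5 + (0:5) / 5, each = seg_len_eeg)
      for (ch in profile$coupled_eeg)
        eeg[ch, ] <- eeg[ch, ] + gain_eeg * latent_eeg
      for (ch in profile$coupled_emg[[movement]])
        emg[ch, ] <- emg[ch, ] + gain * latent
    }
    trial_recording(eeg, emg, movement, subject_id, group,
                    eeg_rate = eeg_rate, emg_rate = emg_rate)
  })
}

#' Generate a balanced synthetic dataset
#'
#' `n_per_class` push and `n_per_class` pull trials for every subject, with
#' subject and group metadata populated and per-trial seeds derived
#' reproducibly from the master seed. Groups may use different generator
#' profiles (e.g. [patient_profile()] for `"patient"`).
#'
#' @param n_per_class Trials per movement class per subject, >= 1.
#' @param subjects Character vector of subject ids.
#' @param group_mix Group per subject: a single group name recycled, or a
#'   vector the length of `subjects` with values `"healthy"`/`"patient"`.
#' @param profile A [generator_profile()], or a named list of profiles by
#'   group (e.g. `list(healthy = ..., patient = ...)`).
#' @param seed Integer master seed.
#' @return List of [trial_recording()] objects with unique `trial_id`s.
#' @export
generate_dataset <- function(n_per_class, subjects, group_mix = "healthy",
                             profile = generator_profile(), seed = 1L) {
  if (length(subjects) == 0L) stop("subject list is empty")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  groups <- rep_len(as.character(group_mix), length(subjects))
  stopifnot(all(groups %in% group_levels))
  profiles <- if (inherits(profile, "generator_profile"))
    stats::setNames(rep(list(profile), 2L), group_levels)
  else profile
  n_trials <- length(subjects) * 2L * n_per_class
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_trials))
  trials <- vector("list", n_trials)
  k <- 0L
  for (si in seq_along(subjects)) {
    for (mv in movement_levels) {
      for (r in seq_len(n_per_class)) {
        k <- k + 1L
        trials[[k]] <- generate_trial(
          mv, profiles[[groups[si]]], seed = trial_seeds[k],
          subject_id = subjects[si], group = groups[si])
        trials[[k]]$trial_id <- sprintf("%s_%s_%03d", subjects[si], mv, r)
      }
    }
  }
  trials
}

#' Write / read a trial dataset (plain-text container)
#'
#' The on-disk layout is a directory holding `manifest.tsv` (one row per
#' trial: trial_id, subject_id, group, movement, rates, file names) and one
#' TSV matrix per trial per modality, channels as rows with channel names in
#' the first column. Samples are printed with 17 significant digits so
#' doubles round-trip exactly: `read_dataset(write_dataset(x)) == x` for any
#' trial with a populated `trial_id` (a blank id is assigned
#' `trial<NNNN>` at write time so files can be named).
#'
#' @param trials List of [trial_recording()] objects.
#' @param path Dataset directory (created if missing).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the list of trials.
#' @export
write_dataset <- function(trials, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    id <- if (nzchar(tr$trial_id)) tr$trial_id else sprintf("trial%04d", i)
    eeg_file <- sprintf("%s_eeg.tsv", id)
    emg_file <- sprintf("%s_emg.tsv", id)
    write_matrix_tsv(tr$eeg, file.path(path, eeg_file))
    write_matrix_tsv(tr$emg, file.path(path, emg_file))
    data.frame(trial_id = id, subject_id = tr$subject_id, group = tr$group,
               movement = tr$movement, eeg_rate = tr$eeg_rate,
               emg_rate = tr$emg_rate, eeg_file = eeg_file,
               emg_file = emg_file)
  })
  utils::write.table(do.call(rbind, rows), file.path(path, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  manifest_path <- file.path(path, "manifest.tsv")
  if (!file.exists(manifest_path))
    stop("malformed dataset: missing ", manifest_path)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                colClasses = "character")
  required <- c("trial_id", "subject_id", "group", "movement", "eeg_rate",
                "emg_rate", "eeg_file", "emg_file")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("malformed dataset: ", manifest_path, " lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    eeg <- read_matrix_tsv(file.path(path, row$eeg_file))
    emg <- read_matrix_tsv(file.path(path, row$emg_file))
    trial_recording(eeg, emg, row$movement, row$subject_id, row$group,
                    eeg_rate = as.numeric(row$eeg_rate),
                    emg_rate = as.numeric(row$emg_rate),
                    trial_id = row$trial_id)
  })
}

write_matrix_tsv <- function(mat, path) {
  ch <- rownames(mat)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(mat)))
  lines <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(ch[i], sprintf("%.17g", mat[i, ])), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("malformed dataset: missing matrix file ", path)
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1L || ncols[1L] < 2L)
    stop("malformed dataset: ragged or empty matrix file ", path)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(ncols[1L] - 1L)))
  if (anyNA(mat)) stop("malformed dataset: non-numeric samples in ", path)
  rownames(mat) <- vapply(parts, `[[`, character(1), 1L)
  mat
}
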