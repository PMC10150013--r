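test_that("generated trials have the acquisition geometry and are seed-deterministic", {
  p <- generator_profile()
  tr <- generate_trial("push", p, seed = 7)
  expect_identical(dim(tr$eeg), c(32L, 1500L))
  expect_identical(dim(tr$emg), c(8L, 3000L))
  expect_identical(tr$eeg_rate, 500)
  expect_identical(tr$emg_rate, 1000)
  expect_true(all(is.finite(tr$eeg)) && all(is.finite(tr$emg)))
  expect_identical(rownames(tr$eeg), eeg_channel_names)
  expect_identical(rownames(tr$emg), emg_channel_names)
  # bit-identical regeneration
  expect_identical(tr, generate_trial("push", p, seed = 7))
  # different seed or movement changes the data
  expect_false(identical(tr$eeg, generate_trial("push", p, seed = 8)$eeg))
  expect_error(generator_profile(noise_sd = 0), "noise_sd")
  expect_error(generator_profile(noise_sd = -1), "noise_sd")
})

test_that("planted coupling raises SPMI between the designated EEG-EMG pair", {
  # SPMI is computed where the pipeline computes it: on preprocessed
  # (resampled + band-passed) segments; the coupling gain ramps up, so the
  # later segments carry the planted dependence most clearly
  cfg <- ordinal_config(5, 1)
  spmi_pair <- function(coupling, seeds) {
    p <- generator_profile(coupling = coupling)
    unlist(lapply(seeds, function(s) {
      segs <- preprocess_trial(generate_trial("push", p, seed = s))
      vapply(segs[4:6], function(seg)
        spmi(seg$data[13, ], seg$data[33, ], cfg), numeric(1))  # C3 vs FDS
    }))
  }
  off <- spmi_pair(0, 1:10)
  on <- spmi_pair(4, 1:10)
  expect_gt(mean(on), mean(off))
  # monotone response: a stronger drive does not reduce the mean coupling
  stronger <- spmi_pair(8, 1:10)
  expect_gte(mean(stronger), mean(on))
})

test_that("planted alpha-band class contrast is resolvable from segment PSDs", {
  # empirical alpha fraction of the final segment differs between classes by
  # more than 3x its Monte-Carlo standard error over 50 trials
  alpha_frac <- function(movement, seed) {
    tr <- generate_trial(movement, generator_profile(), seed = seed)
    seg <- tr$eeg[1, 1251:1500]  # channel Fp1, segment 5
    est <- multitaper_psd(seg, 500)
    unname(band_fractions(est$frequencies, est$psd)$fractions["alpha"])
  }
  push <- vapply(1:25, function(s) alpha_frac("push", s), numeric(1))
  pull <- vapply(26:50, function(s) alpha_frac("pull", s), numeric(1))
  diff_mean <- mean(push) - mean(pull)
  se <- sqrt(var(push) / 25 + var(pull) / 25)
  expect_gt(abs(diff_mean), 3 * se)
  expect_gt(diff_mean, 0)  # push alpha ramps up to 3x by the final segment
})

test_that("datasets are balanced, tagged and reproducible", {
  trials <- generate_dataset(2, c("a", "b"), "healthy", seed = 5)
  expect_length(trials, 8L)  # 2 per class x 2 classes x 2 subjects
  moves <- vapply(trials, `[[`, character(1), "movement")
  subj <- vapply(trials, `[[`, character(1), "subject_id")
  expect_identical(unname(table(moves, subj)["push", "a"]), 2L)
  expect_true(all(vapply(trials, `[[`, character(1), "group") == "healthy"))
  expect_true(anyDuplicated(vapply(trials, `[[`, character(1), "trial_id")) == 0)
  trials2 <- generate_dataset(2, c("a", "b"), "healthy", seed = 5)
  expect_identical(trials, trials2)
  expect_error(generate_dataset(2, character(0)), "empty")
  expect_error(generate_dataset(0, "a"), "n_per_class")
  # per-group profiles
  mixed <- generate_dataset(1, c("h", "p"), c("healthy", "patient"),
                            list(healthy = generator_profile(),
                                 patient = patient_profile()), seed = 2)
  expect_identical(vapply(mixed, `[[`, character(1), "group"),
                   rep(c("healthy", "patient"), each = 2))
})

test_that("the patient profile is a strictly degraded copy of the healthy one", {
  h <- generator_profile()
  p <- patient_profile(h)
  expect_gt(p$noise_sd, h$noise_sd)
  expect_lt(p$coupling, h$coupling)
  # contrast attenuated: weight deviations from baseline shrink
  expect_lt(max(abs(p$band_weights - 1)), max(abs(h$band_weights - 1)))
})

test_that("dataset serialization round-trips exactly and flags malformed layouts", {
  trials <- generate_dataset(1, c("s1", "s2"), "healthy", seed = 9)
  trials <- c(trials, generate_dataset(1, "s3", "patient", patient_profile(),
                                       seed = 10)[1])
  path <- withr::local_tempdir()
  write_dataset(trials, path)
  back <- read_dataset(path)
  expect_identical(trials, back)
  # missing metadata column
  man <- read.table(file.path(path, "manifest.tsv"), sep = "\t", header = TRUE)
  write.table(man[, setdiff(names(man), "movement")],
              file.path(path, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(path), "lacks column")
  expect_error(read_dataset(file.path(path, "nope")), "missing")
})

test_that("EDF fixtures round-trip with header-derived rates", {
  tr <- generate_trial("pull", generator_profile(), seed = 4, group = "patient")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(tr, path)
  back <- read_edf_trial(path, "pull", subject_id = tr$subject_id,
                         group = "patient")
  expect_identical(back$eeg_rate, 500)
  expect_identical(back$emg_rate, 1000)
  expect_identical(dim(back$eeg), dim(tr$eeg))
  expect_identical(rownames(back$emg), emg_channel_names)
  # 16-bit quantization: agreement to ~range/2^15
  expect_lt(max(abs(back$eeg - tr$eeg)), diff(range(tr$eeg)) / 2^14)
  expect_error(read_edf(path <- withr::local_tempfile(lines = "not an edf")),
               "EDF")
})
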