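# Reading, montage mapping, standardisation, epoching and QC rejection.

test_that("records round-trip through the WFDB-style writer", {
  dir <- withr::local_tempdir()
  m <- patient_meta("p01", hospital = 2, age = 58, sex = "Female", rosc = 18,
                    ohca = TRUE, shockable = FALSE, ttm = 33, cpc = 2)
  rec <- eeg_recording(matrix(rnorm(19 * 128 * 30, sd = 25), 19),
                       eeg_channels(), 128, start_hour = 1, hour_s = 30, meta = m)
  write_record(rec, file.path(dir, "p01"))
  back <- read_record(file.path(dir, "p01"))
  expect_lte(max(abs(back$recording$signal - rec$signal)), 1 / 32)
  expect_equal(back$recording$fs, 128)
  expect_equal(back$recording$start_hour, 1)
  expect_equal(back$recording$hour_s, 30)
  expect_equal(back$meta$cpc, 2)
  expect_identical(back$meta$label, "good")
  expect_identical(back$meta$shockable, FALSE)
  expect_error(read_record(file.path(dir, "absent")), "header")
})

test_that("missing sidecar fields stay missing, never defaulted", {
  dir <- withr::local_tempdir()
  writeLines(c("Patient: p02", "Age: 61", "CPC: 5"), file.path(dir, "p02.txt"))
  m <- qeegprog:::read_meta_sidecar(file.path(dir, "p02.txt"))
  expect_true(is.na(m$shockable))
  expect_true(is.na(m$rosc))
  expect_equal(m$age, 61)
  expect_identical(m$label, "poor")
})

test_that("montage mapping reorders, translates aliases and drops extras", {
  set.seed(10)
  labs <- c("ECG", sample(c(setdiff(eeg_channels(), c("T3", "T4", "T5", "T6")),
                            "T7", "T8", "P7", "P8")), "A1")
  raw <- eeg_recording(matrix(seq_len(length(labs) * 10), length(labs)),
                       labs, 128, hour_s = 30)
  std <- map_montage(raw)
  expect_identical(std$channels, eeg_channels())
  # the row that carried "T7" must now sit at position of "T3"
  expect_equal(std$signal[which(eeg_channels() == "T3"), ],
               raw$signal[which(labs == "T7"), ])
  bad <- eeg_recording(raw$signal[labs != "P7", ], labs[labs != "P7"], 128)
  expect_error(map_montage(bad), "T5")
})

test_that("standardisation filters, resamples and references", {
  fs <- 512
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  sig <- matrix(rep(50 * sin(2 * pi * 60 * t), 19), 19, byrow = TRUE) +
    matrix(rnorm(19 * n), 19) + 30  # mains + noise + DC
  rec <- eeg_recording(sig, eeg_channels(), fs, hour_s = 20)
  out <- preprocess(rec)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$signal), 20 * 256)
  # average reference: per-sample channel mean ~ 0
  expect_lt(max(abs(colMeans(out$signal))), 1e-6)
  # DC removed
  expect_lt(max(abs(rowMeans(out$signal))), 0.1)
  # 60 Hz down by >= 40 dB
  pin <- qeegprog:::welch_psd(sig[1, , drop = FALSE], fs, fs)
  pout <- qeegprog:::welch_psd(out$signal[1, , drop = FALSE], 256, 256)
  att <- 10 * log10(pout$psd[which.min(abs(pout$freq - 60)), 1] /
                      pin$psd[which.min(abs(pin$freq - 60)), 1])
  expect_lt(att, -40)
  short <- eeg_recording(sig[, 1:(5 * fs)], eeg_channels(), fs)
  expect_error(preprocess(short), "10 s")
})

test_that("standardisation is idempotent up to filter tolerance", {
  rec <- tiny_cohort()$records[[1]]
  cfgfs <- rec$fs
  once <- preprocess(map_montage(rec), fs_target = cfgfs)
  twice <- preprocess(once, fs_target = cfgfs)
  rms <- sqrt(mean(once$signal^2))
  expect_lt(sqrt(mean((twice$signal - once$signal)^2)) / rms, 0.05)
})

test_that("epoch counts follow the recording length", {
  one_hour <- eeg_recording(matrix(rnorm(256 * 3600), 1), "Cz", 256)
  expect_equal(dim(make_epochs(one_hour, 2)$epochs)[3], 1800)
  expect_equal(dim(make_epochs(one_hour, 30)$epochs)[3], 120)
  odd <- eeg_recording(matrix(rnorm(128 * 61), 1), "Cz", 128)
  expect_equal(dim(make_epochs(odd, 30)$epochs)[3], 2)
})

test_that("epoch rejection keeps exactly the in-range epochs", {
  fs <- 128
  sig <- matrix(rnorm(19 * 120 * fs, sd = 20), 19)
  ar <- inject_artifacts(sig, 0.12, 0.08, fs, seed = 3)
  rec <- eeg_recording(ar$signal, eeg_channels(), fs, hour_s = 120)
  eps <- reject_epochs(make_epochs(rec, 2))
  expect_identical(!eps$keep, ar$artifact_mask != "none")
  expect_equal(eps$retention, mean(ar$artifact_mask == "none"))
  # channel permutation does not change keep flags
  perm <- sample(19)
  rec2 <- eeg_recording(ar$signal[perm, ], eeg_channels()[perm], fs, hour_s = 120)
  eps2 <- reject_epochs(make_epochs(rec2, 2))
  expect_identical(eps$keep, eps2$keep)
  # clean and flat extremes
  clean <- reject_epochs(make_epochs(eeg_recording(sig, eeg_channels(), fs), 2))
  expect_equal(clean$retention, 1)
  flat <- reject_epochs(make_epochs(eeg_recording(sig * 0, eeg_channels(), fs), 2))
  expect_equal(flat$retention, 0)
})

test_that("the retention gate reads 'less than 30%' strictly", {
  eps <- structure(list(retention = 0.29), class = "epoch_set")
  expect_false(retention_gate(eps))
  eps$retention <- 0.30
  expect_true(retention_gate(eps))
  eps$retention <- 1
  expect_true(retention_gate(eps))
})

test_that("epoch tiling reconstructs the hour minus the remainder", {
  fs <- 128
  rec <- eeg_recording(matrix(seq_len(19 * 61 * fs), 19), eeg_channels(), fs)
  eps <- make_epochs(rec, 2)
  n_ep <- dim(eps$epochs)[3]
  rebuilt <- matrix(eps$epochs, 19, n_ep * 2 * fs)
  expect_equal(rebuilt, rec$signal[, seq_len(n_ep * 2 * fs)])
})
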