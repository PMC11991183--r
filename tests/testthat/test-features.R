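# Spectral band power, magnitude-squared coherence and burst suppression
# ratio against analytic and planted oracles.

test_that("band power recovers a pure sinusoid and is Parseval-consistent", {
  fs <- 256
  t <- (seq_len(2 * fs) - 1) / fs
  ep <- rbind(sin(2 * pi * 10 * t), 0)
  bp <- welch_band_power(ep, fs)
  expect_lt(abs(bp[1, "alpha"] - 0.5) / 0.5, 0.1)
  expect_lt(max(bp[1, c("delta", "theta", "beta", "gamma")]), 0.05 * bp[1, "alpha"])
  expect_equal(unname(bp[2, ]), rep(0, 5))
  # five-band sum equals total [0.5, 45] power
  x <- synth_channel_noise(c(10, 8, 6, 4, 2), 2, fs, seed = 11)
  bp2 <- welch_band_power(matrix(x, 1), fs)
  ps <- qeegprog:::welch_psd(matrix(x, 1), fs, fs)
  total <- sum(ps$psd[ps$freq >= 0.5 & ps$freq <= 45, 1]) * (fs / fs)
  expect_lt(abs(sum(bp2) - total) / total, 0.02)
  expect_error(welch_band_power(matrix(c(NA, rnorm(2 * fs - 1)), 1), fs), "QC")
})

test_that("white-noise band power is proportional to bandwidth", {
  fs <- 256
  set.seed(12)
  acc <- rep(0, 5)
  for (i in 1:400) acc <- acc + welch_band_power(matrix(rnorm(2 * fs), 1), fs)[1, ]
  acc <- acc / 400
  # the 1 Hz grid covers 3 of delta's 3.5 Hz; compare per-covered-Hz density
  covered <- c(3, 4, 5, 17, 15)
  dens <- acc / covered
  expect_lt(max(dens) / min(dens), 1.2)
})

test_that("MSC is 1 on identity, symmetric and scale invariant", {
  fs <- 128
  x <- synth_channel_noise(rep(10, 5), 30, fs, seed = 13)
  y <- synth_channel_noise(rep(10, 5), 30, fs, seed = 14)
  expect_true(all(msc_pair(x, x, fs) > 1 - 1e-9))
  expect_equal(msc_pair(x, y, fs), msc_pair(y, x, fs))
  expect_equal(msc_pair(3.7 * x, y, fs), msc_pair(x, y, fs), tolerance = 1e-12)
  expect_warning(m0 <- msc_pair(numeric(30 * fs), x, fs), "zero-variance")
  expect_true(all(is.na(m0)))
})

test_that("MSC matches the planted closed form and the 1/K independence bias", {
  fs <- 128
  K <- feature_config()$coh_segments
  base <- matrix(0, 2, 30 * fs)
  est <- rep(0, 2)
  set.seed(15)
  n_ep <- 40
  for (i in seq_len(n_ep)) {
    inj <- inject_coherent_source(base, 1, 1, c(1, 1), "delta", fs,
                                  seed = sample.int(1e6, 1))
    est[1] <- est[1] + msc_pair(inj$signals[1, ], inj$signals[2, ], fs)["delta"]
    est[2] <- est[2] + msc_pair(rnorm(30 * fs), rnorm(30 * fs), fs)["delta"]
  }
  est <- est / n_ep
  expect_lt(abs(est[1] - 0.25), 0.06)   # wider than the acceptance band: 40 epochs
  expect_lt(abs(est[2] - 1 / K), 0.03)
})

test_that("hourly connectivity singles out a planted coherent pair", {
  fs <- 128
  n <- 120 * fs
  cfg <- feature_config(fs_target = fs, hour_s = 120)
  sig <- vapply(seq_len(19), function(i)
    synth_channel_noise(c(20, 10, 10, 5, 3), 120, fs, seed = 100 + i),
    numeric(n))
  sig <- t(sig)
  inj <- inject_coherent_source(sig[c(3, 8), ], 1, 12, c(4, 4), "delta", fs,
                                seed = 16)
  sig[c(3, 8), ] <- inj$signals
  rec <- eeg_recording(sig, eeg_channels(), fs, hour_s = 120)
  eps <- reject_epochs(make_epochs(rec, 30))
  fc <- hourly_connectivity(eps, cfg)
  pairs <- channel_pairs()
  planted_row <- which(pairs$ia == 3 & pairs$ib == 8)
  others <- fc[-planted_row, "delta"]
  expect_gt(fc[planted_row, "delta"], quantile(others, 0.99))
  # all-identical channels give MSC 1 for every pair
  same <- eeg_recording(matrix(rep(sig[1, ], 19), 19, byrow = TRUE),
                        eeg_channels(), fs, hour_s = 120)
  fc1 <- hourly_connectivity(reject_epochs(make_epochs(same, 30)), cfg)
  expect_true(all(fc1 > 1 - 1e-9))
  expect_equal(nrow(fc1), 171)
})

test_that("BSR recovers planted occupancy and is monotone in threshold", {
  fs <- 128
  cfg <- feature_config(fs_target = fs, hour_s = 600)
  sig <- matrix(rnorm(600 * fs, sd = 30), 1)
  bs <- inject_burst_suppression(sig, 0.4, mean_burst_s = 6, fs = fs, seed = 17)
  b <- bsr_hour(bs$signal, cfg)
  expect_lt(abs(b[1, "15uV"] - mean(bs$state)), 0.05)
  expect_true(all(diff(b[1, ]) >= 0))
  flat <- bsr_hour(matrix(0, 1, 600 * fs), cfg)
  expect_equal(unname(flat[1, ]), rep(1, 3))
  loud <- bsr_hour(matrix(rnorm(600 * fs, sd = 100), 1), cfg)
  expect_equal(unname(loud[1, ]), rep(0, 3))
  # random signals never violate threshold nesting
  set.seed(18)
  for (i in 1:5) {
    r <- bsr_hour(matrix(rnorm(60 * fs, sd = runif(1, 1, 40)), 1),
                  feature_config(fs_target = fs, hour_s = 60))
    expect_true(all(diff(r[1, ]) >= 0))
  }
})

test_that("patient extraction yields full-dimension tensors with null tails", {
  tl <- tiny_tensors()
  ft <- tl[[1]]
  expect_equal(dim(ft$psd), c(19, 5, 72))
  expect_equal(dim(ft$fc), c(171, 5, 72))
  expect_equal(dim(ft$bsr), c(19, 3, 72))
  # 6 h recordings: hours 6..71 are null
  expect_true(all(!ft$null_hours[1:6]))
  expect_true(all(ft$null_hours[7:72]))
  expect_true(all(is.na(ft$psd[, , 7:72])))
  expect_true(all(ft$fc[, , 1:6] >= 0 & ft$fc[, , 1:6] <= 1))
  expect_true(all(ft$psd[, , 1:6] >= 0))
  expect_true(all(ft$bsr[, , 1:6] >= 0 & ft$bsr[, , 1:6] <= 1))
})

test_that("a gated-out hour is null end to end", {
  fs <- 128
  flat <- matrix(0, 19, 60 * fs)  # everything below 1 uV p2p -> retention 0
  rec <- eeg_recording(flat, eeg_channels(), fs, hour_s = 60)
  cfg <- feature_config(fs_target = fs, hour_s = 60)
  ft <- extract_patient(rec, cfg, preprocessed = TRUE)
  expect_true(ft$null_hours[1])
  expect_true(all(is.na(ft$psd[, , 1])))
  expect_equal(ft$retention[1], 0)
})
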