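# Synthetic cohort generator: determinism, ground-truth invariants, and the
# signal-level injection operators against their closed-form oracles.

test_that("cohorts are bit-identical under a fixed seed", {
  cc <- cohort_config(n_patients = 3, duration_h = 2, fs = 128, hour_s = 30,
                      seed = 7)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$records[[1]]$signal, b$records[[1]]$signal)
  expect_identical(a$truth, b$truth)
})

test_that("good_fraction boundaries produce pure cohorts with matching CPC", {
  cc <- cohort_config(n_patients = 10, duration_h = 1, fs = 128, hour_s = 30,
                      seed = 3, good_fraction = 1)
  tr <- generate_cohort(cc)$truth
  expect_true(all(vapply(tr, `[[`, character(1), "label") == "good"))
  expect_true(all(vapply(tr, `[[`, numeric(1), "cpc") %in% c(1, 2)))
  cc0 <- cohort_config(n_patients = 6, duration_h = 1, fs = 128, hour_s = 30,
                       seed = 3, good_fraction = 0)
  tr0 <- generate_cohort(cc0)$truth
  expect_true(all(vapply(tr0, `[[`, numeric(1), "cpc") %in% 3:5))
})

test_that("ground truth obeys its range invariants", {
  tr <- tiny_cohort()$truth
  for (t in tr) {
    expect_true(all(t$band_power >= 0))
    expect_true(all(t$pair_msc >= 0 & t$pair_msc <= 1))
    expect_true(all(t$bsr_occupancy >= 0 & t$bsr_occupancy <= 1))
    expect_true(t$cpc %in% 1:5)
    expect_identical(t$label, ifelse(t$cpc <= 2, "good", "poor"))
  }
})

test_that("planted suppression occupancy separates the groups at every hour", {
  cc <- cohort_config(n_patients = 40, duration_h = 3, fs = 128, hour_s = 30,
                      seed = 99, good_fraction = 0.45)
  tr <- generate_cohort(cc)$truth
  lab <- vapply(tr, `[[`, character(1), "label")
  occ <- vapply(tr, `[[`, numeric(3), "bsr_occupancy")
  expect_true(all(rowMeans(occ[, lab == "poor"]) > rowMeans(occ[, lab == "good"])))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(0), "n_patients")
  expect_error(cohort_config(5, good_fraction = 1.2), "good_fraction")
  expect_error(cohort_config(5, fs = 80), "fs")
})

test_that("channel noise hits the requested band powers", {
  fs <- 256
  expect_identical(synth_channel_noise(rep(0, 5), 2, fs, seed = 1),
                   numeric(2 * fs))
  x <- synth_channel_noise(c(0, 0, 10, 0, 0), 60, fs, seed = 2)
  bp <- rowMeans(vapply(seq_len(30), function(e) {
    welch_band_power(x[((e - 1) * 2 * fs + 1):(e * 2 * fs)], fs)[1, ]
  }, numeric(5)))
  expect_lt(abs(bp["alpha"] - 10) / 10, 0.15)
  # resolving a 3.5 Hz-wide band ratio needs a finer grid than the 2 s
  # epochs' 1 Hz: estimate on the full signal with 4 s segments
  y <- synth_channel_noise(c(8, 2, 0, 0, 0), 60, fs, seed = 3)
  bpy <- welch_band_power(matrix(y, 1), fs, seg_s = 4)[1, ]
  expect_lt(abs(bpy["delta"] / bpy["theta"] - 4) / 4, 0.2)
  expect_error(synth_channel_noise(c(-1, 0, 0, 0, 0), 1, fs), "non-negative")
})

test_that("coherent source injection matches its closed form", {
  fs <- 128
  base <- matrix(0, 2, 30 * fs)
  expect_equal(inject_coherent_source(base, 0, 1, c(1, 1), "delta", fs)$expected_msc, 0)
  expect_equal(inject_coherent_source(base, 1, 1, c(0, 0), "delta", fs)$expected_msc, 1)
  inj <- inject_coherent_source(base, 1, 1, c(1, 1), "delta", fs)
  expect_equal(inj$expected_msc, 0.25)
  # noiseless mixing gives estimated MSC = 1 in the injected band
  perfect <- inject_coherent_source(base, 2, 1, c(0, 0), "theta", fs, seed = 4)
  m <- msc_pair(perfect$signals[1, ], perfect$signals[2, ], fs)
  expect_gt(m["theta"], 0.999)
  expect_error(inject_coherent_source(base, 1, 1, c(1, 1), c(40, 60), fs),
               "outside")
})

test_that("burst suppression injection realises the requested occupancy", {
  fs <- 128
  sig <- matrix(rnorm(2 * 3600 * fs, sd = 30), 2)
  none <- inject_burst_suppression(sig, 0, fs = fs)
  expect_identical(none$signal, sig)
  expect_false(any(none$state))
  full <- inject_burst_suppression(sig, 1, fs = fs)
  expect_true(all(full$state))
  expect_equal(full$signal, sig * 0.02)
  bs <- inject_burst_suppression(sig, 0.4, fs = fs, seed = 5)
  expect_lt(abs(mean(bs$state) - 0.4), 0.05)
  expect_error(inject_burst_suppression(sig, 0.4, supp_scale = 1, fs = fs),
               "supp_scale")
})

test_that("artifact injection marks exactly the altered epochs", {
  fs <- 128
  sig <- matrix(rnorm(19 * 120 * fs, sd = 20), 19)
  id <- inject_artifacts(sig, 0, 0, fs)
  expect_identical(id$signal, sig)
  expect_true(all(id$artifact_mask == "none"))
  ar <- inject_artifacts(sig, 0.15, 0.1, fs, seed = 8)
  L <- 2 * fs
  p2p <- vapply(seq_along(ar$artifact_mask), function(e) {
    seg <- ar$signal[, ((e - 1) * L + 1):(e * L), drop = FALSE]
    max(apply(seg, 1, function(r) max(r) - min(r)))
  }, numeric(1))
  expect_true(any(ar$artifact_mask == "high") && any(ar$artifact_mask == "flat"))
  expect_true(all(p2p[ar$artifact_mask == "high"] > 300))
  expect_true(all(p2p[ar$artifact_mask == "flat"] < 1))
  expect_true(all(p2p[ar$artifact_mask == "none"] <= 300 &
                    p2p[ar$artifact_mask == "none"] >= 1))
})

test_that("short-duration patients are generated when requested", {
  cc <- cohort_config(n_patients = 10, duration_h = 6, fs = 128, hour_s = 30,
                      seed = 17, short_fraction = 0.3)
  tr <- generate_cohort(cc)$truth
  dur <- vapply(tr, `[[`, numeric(1), "duration_h")
  expect_equal(sum(dur < 5), 3)
})
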