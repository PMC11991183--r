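# Synthetic EEG cohort generator. Emulates the statistical structure the
# pipeline measures in post-cardiac-arrest continuous EEG: per-band power
# trajectories that differ by prognosis group, pairwise coherent sources with
# known mixing, a two-state burst/suppression process with known occupancy,
# amplitude artifacts, hospitals, clinical covariates and CPC outcome labels.
# The per-group default profiles follow the contrasts reported for real
# cohorts: the good-outcome group has higher broadband power with a theta rise
# peaking near 20 h and a burst suppression ratio that falls quickly to ~10%,
# while the poor-outcome group shows elevated low-frequency long-distance
# coherence and suppression occupancy staying above ~20%.

# Disjoint long-distance channel pairs carrying the planted low-frequency
# coherent sources. Disjointness keeps the closed-form coherence oracle exact
# (no channel participates in two sources).
planted_fc_pairs <- function() {
  data.frame(a = c("Fp1", "Fp2", "F7", "F8", "F3", "F4"),
             b = c("O1",  "O2",  "T6", "T5", "P4", "P3"),
             stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients (>= 1).
#' @param n_hospitals number of hospitals, assigned uniformly at random
#'   (default 5).
#' @param duration_h hours of EEG per patient (default 72).
#' @param fs sampling rate in Hz, > 90 (default 256).
#' @param hour_s seconds of signal generated per hour bin (default 3600; small
#'   values compress the cohort for desk-scale experiments while keeping the
#'   per-hour statistical structure).
#' @param seed integer master seed; cohorts are bit-identical for a fixed seed.
#' @param good_fraction proportion of good-outcome (CPC 1-2) patients; default
#'   0.37, the good-outcome prevalence in the source cohort.
#' @param short_fraction proportion of patients given < 5 h of data (to
#'   exercise the minimum-duration exclusion filter); default 0.
#' @param high_amp_rate,flat_rate per-2 s-epoch artifact probabilities.
#' @param profiles optional list overriding per-group generative profiles; see
#'   [default_profiles()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, n_hospitals = 5, duration_h = 72,
                          fs = 256, hour_s = 3600, seed = 1,
                          good_fraction = 0.37, short_fraction = 0,
                          high_amp_rate = 0.01, flat_rate = 0.005,
                          profiles = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (good_fraction < 0 || good_fraction > 1) stop("good_fraction must be in [0, 1]")
  if (short_fraction < 0 || short_fraction > 1) stop("short_fraction must be in [0, 1]")
  if (fs <= 90) stop("fs must exceed 90 Hz")
  if (n_hospitals < 1) stop("n_hospitals must be >= 1")
  prof <- default_profiles()
  if (!is.null(profiles)) prof[names(profiles)] <- profiles
  structure(list(n_patients = as.integer(n_patients),
                 n_hospitals = as.integer(n_hospitals),
                 duration_h = as.integer(duration_h), fs = fs,
                 hour_s = hour_s, seed = seed,
                 good_fraction = good_fraction,
                 short_fraction = short_fraction,
                 high_amp_rate = high_amp_rate, flat_rate = flat_rate,
                 profiles = prof),
            class = "cohort_config")
}

#' Default per-group generative profiles
#'
#' Hourly band-power trajectories (uV^2 per channel), planted pair coherence,
#' burst-suppression occupancy trajectories and clinical covariate
#' distributions for the good and poor prognosis groups.
#'
#' @return named list of profile functions and parameters.
#' @export
default_profiles <- function() {
  list(
    # band powers as a function of hour (0-based), returning length-5 vector.
    # Group means differ (poor: globally weaker, low-frequency dominant; good:
    # theta rise peaking near 20 h) but the per-patient amplitude scale varies
    # several-fold (patient_scale_sd below), so single-patient band power
    # overlaps heavily between groups: the crisp group discriminator is the
    # planted coherence, matching the attribution structure seen in real
    # cohorts where connectivity dominates and raw power contributes little.
    band_power_good = function(h) {
      c(delta = 250, theta = 200 + 150 * exp(-(h - 20)^2 / (2 * 10^2)),
        alpha = 200, beta = 150, gamma = 100)
    },
    band_power_poor = function(h) {
      c(delta = 230, theta = 130 + 60 * h / 72, alpha = 130, beta = 90, gamma = 50)
    },
    # planted low-frequency long-distance coherence (delta band)
    fc_band = "delta",
    fc_msc_good = 0.10,
    fc_msc_poor = 0.55,
    fc_msc_jitter = 0.05,
    # suppression occupancy trajectories (poor stays above ~20%, rises late)
    bsr_occ_good = function(h) 0.35 * exp(-h / 10) + 0.08,
    bsr_occ_poor = function(h) 0.50 * exp(-h / 30) + 0.22 + 0.10 * pmax(0, (h - 60) / 12),
    bsr_jitter = 0.45,      # multiplicative log-normal sd on occupancy
    power_jitter = 0.15,    # per-channel multiplicative log-normal sd
    patient_scale_sd = 0.5, # per-patient global amplitude log-normal sd
    band_mix_sd = 0.4,      # per-patient per-band mix log-normal sd
    mean_burst_s = 2,
    # 0.05 (not the injector's 0.02 default): with several-fold per-patient
    # amplitude variation, a 0.02 scale pushes suppressed stretches of
    # low-amplitude patients under the 1 uV flatline bound, and QC would
    # reject genuine suppression as artifact
    supp_scale = 0.05,
    age_good = c(mean = 55, sd = 14),
    age_poor = c(mean = 66, sd = 13),
    shockable_good = 0.7,
    shockable_poor = 0.3,
    cpc_good_probs = c(`1` = 0.6, `2` = 0.4),
    cpc_poor_probs = c(`3` = 0.05, `4` = 0.03, `5` = 0.92)
  )
}

#' Generate a synthetic EEG cohort with ground truth
#'
#' Produces one multichannel recording per patient (19-channel 10-20 montage)
#' plus a ground-truth object holding, per patient: hourly per-channel band
#' powers, the planted pair coherence matrix (171 pairs x 5 bands), hourly
#' suppression occupancy, the CPC outcome and clinical covariates. Fixed seeds
#' give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return list with `records` (list of `eeg_recording` objects, each carrying
#'   a `meta` attribute) and `truth` (class `cohort_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  prof <- config$profiles
  ch <- eeg_channels()
  pairs <- channel_pairs()
  fc_pairs <- planted_fc_pairs()
  fc_band_i <- match(prof$fc_band, eeg_bands()$band)
  n <- config$n_patients

  pt <- with_seed(child_seed(config$seed, 0), {
    n_good <- round(config$good_fraction * n)
    lab <- rep("poor", n)
    if (n_good > 0) lab[sample.int(n, n_good)] <- "good"
    n_short <- round(config$short_fraction * n)
    short <- rep(FALSE, n)
    if (n_short > 0) short[sample.int(n, n_short)] <- TRUE
    list(label = lab, short = short,
         hospital = sample.int(config$n_hospitals, n, replace = TRUE))
  })

  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_patient(i, pt$label[i], pt$short[i], pt$hospital[i], config)
    records[[i]] <- g$record
    truth[[i]] <- g$truth
  }
  names(records) <- vapply(truth, function(t) t$id, character(1))
  structure(list(records = records,
                 truth = structure(truth, class = "cohort_truth"),
                 config = config),
            class = "eeg_cohort")
}

generate_patient <- function(i, label, short, hospital, config) {
  prof <- config$profiles
  fs <- config$fs
  hour_s <- config$hour_s
  ch <- eeg_channels()
  nch <- length(ch)
  pairs <- channel_pairs()
  fc_pairs <- planted_fc_pairs()
  bands <- eeg_bands()$band
  fc_band_i <- match(prof$fc_band, bands)
  seed_i <- child_seed(config$seed, i)

  meta <- with_seed(seed_i, {
    cpc_probs <- if (label == "good") prof$cpc_good_probs else prof$cpc_poor_probs
    cpc <- as.integer(sample(names(cpc_probs), 1, prob = cpc_probs))
    agep <- if (label == "good") prof$age_good else prof$age_poor
    shock_p <- if (label == "good") prof$shockable_good else prof$shockable_poor
    list(
      id = sprintf("synth%04d", i),
      hospital = hospital,
      age = round(max(18, stats::rnorm(1, agep["mean"], agep["sd"]))),
      sex = sample(c("Male", "Female"), 1, prob = c(0.65, 0.35)),
      rosc = round(stats::rgamma(1, shape = 2,
                                 scale = if (label == "good") 10 else 17), 1),
      ohca = stats::runif(1) < 0.8,
      shockable = stats::runif(1) < shock_p,
      ttm = sample(c(33, 36, 0), 1, prob = c(0.5, 0.3, 0.2)),
      cpc = cpc
    )
  })

  H <- config$duration_h
  if (short) H <- with_seed(seed_i + 1, sample(2:4, 1))

  # per-patient multiplicative jitters (constant over time)
  jit <- with_seed(seed_i + 2, {
    # the scale jitter is truncated so no patient's amplitude leaves the
    # [1, 300] uV peak-to-peak QC window wholesale: untruncated tails get
    # entire hours rejected, and that attrition would correlate with outcome
    list(power = exp(stats::rnorm(nch, 0, prof$power_jitter)) *
           min(max(exp(stats::rnorm(1, 0, prof$patient_scale_sd)), 0.45), 1.6),
         band_mix = exp(stats::rnorm(5, 0, prof$band_mix_sd)),
         bsr = exp(stats::rnorm(1, 0, prof$bsr_jitter)),
         fc = stats::rnorm(nrow(fc_pairs), 0, prof$fc_msc_jitter))
  })

  msc_target <- if (label == "good") prof$fc_msc_good else prof$fc_msc_poor
  fc_msc <- pmin(pmax(msc_target + jit$fc, 0), 0.9)

  # truth containers
  band_power <- array(NA_real_, c(nch, 5, H), dimnames = list(ch, bands, NULL))
  bsr_occ <- numeric(H)
  pair_msc <- matrix(0, nrow(pairs), 5,
                     dimnames = list(paste(pairs$a, pairs$b, sep = "_"), bands))
  for (p in seq_len(nrow(fc_pairs))) {
    row <- which(pairs$a == fc_pairs$a[p] & pairs$b == fc_pairs$b[p])
    pair_msc[row, fc_band_i] <- fc_msc[p]
  }

  n_hour <- round(hour_s * fs)
  sig <- matrix(0, nch, n_hour * H)
  bpf <- if (label == "good") prof$band_power_good else prof$band_power_poor
  occf <- if (label == "good") prof$bsr_occ_good else prof$bsr_occ_poor
  b <- eeg_bands()

  for (h in seq_len(H) - 1L) {
    hseed <- child_seed(seed_i, 1000 + h)
    target <- bpf(h)
    # per-channel band powers with per-patient channel and band-mix jitter
    pw <- outer(jit$power, target * jit$band_mix)  # nch x 5
    band_power[, , h + 1L] <- pw
    # shared-source variance vs = sqrt(C * Pa * Pb) gives in-band MSC = C
    planted <- data.frame(
      ia = match(fc_pairs$a, ch), ib = match(fc_pairs$b, ch),
      vs = sqrt(fc_msc * pw[match(fc_pairs$a, ch), fc_band_i] *
                  pw[match(fc_pairs$b, ch), fc_band_i]))
    hour_sig <- with_seed(hseed,
      synth_hour_signal(n_hour, fs, pw, planted, fc_band_i))
    occ <- min(0.97, occf(h) * jit$bsr)
    bs <- inject_burst_suppression(hour_sig, occ, mean_burst_s = prof$mean_burst_s,
                                   supp_scale = prof$supp_scale, fs = fs,
                                   seed = child_seed(hseed, 7))
    bsr_occ[h + 1L] <- mean(bs$state)
    ar <- inject_artifacts(bs$signal, config$high_amp_rate, config$flat_rate,
                           fs, seed = child_seed(hseed, 8))
    idx <- (h * n_hour + 1L):((h + 1L) * n_hour)
    sig[, idx] <- ar$signal
  }
  rownames(sig) <- ch

  pm <- patient_meta(id = meta$id, hospital = meta$hospital, age = meta$age,
                     sex = meta$sex, rosc = meta$rosc, ohca = meta$ohca,
                     shockable = meta$shockable, ttm = meta$ttm, cpc = meta$cpc)
  rec <- eeg_recording(sig, channels = ch, fs = fs, start_hour = 0,
                       hour_s = hour_s, meta = pm)
  truth <- list(id = meta$id, label = label, cpc = meta$cpc,
                hospital = meta$hospital, age = meta$age, sex = meta$sex,
                shockable = meta$shockable, ohca = meta$ohca, rosc = meta$rosc,
                ttm = meta$ttm, duration_h = H,
                band_power = band_power, pair_msc = pair_msc,
                bsr_occupancy = bsr_occ)
  list(record = rec, truth = truth)
}

#' Write a cohort to disk as WFDB-style records
#'
#' Each patient becomes a WFDB-format header + 16-bit signal file pair plus a
#' plain-text clinical metadata sidecar; a cohort `manifest.csv` and a
#' ground-truth archive (`truth.rds`) are written alongside.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$truth, function(t) {
    data.frame(id = t$id, hospital = t$hospital, cpc = t$cpc, label = t$label,
               duration_h = t$duration_h, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  for (id in names(cohort$records)) {
    write_record(cohort$records[[id]], file.path(dir, id))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  saveRDS(cohort$truth, file.path(dir, "truth.rds"))
  invisible(manifest)
}
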