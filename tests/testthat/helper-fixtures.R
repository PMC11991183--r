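# Shared fixtures, built once per test run and memoised. Everything is
# generated in code at test time; scales are kept small (compressed hour bins,
# 128 Hz) so the statistical structure is preserved at desk-scale cost.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small cohort exercising the full signal path: 8 patients, 6 h each,
# 60 s hour bins at 128 Hz.
tiny_cohort <- function() {
  get_fixture("tiny_cohort", function() {
    cc <- cohort_config(n_patients = 8, n_hospitals = 3, duration_h = 6,
                        fs = 128, hour_s = 60, seed = 421, good_fraction = 0.5)
    generate_cohort(cc)
  })
}

tiny_tensors <- function() {
  get_fixture("tiny_tensors", function() {
    cfg <- feature_config(fs_target = 128, hour_s = 60)
    lapply(tiny_cohort()$records, extract_patient, cfg = cfg)
  })
}

# Synthetic feature tensors built directly (no signal path) with a given
# constant fill; used by assembly/timecourse tests.
make_tensors <- function(fill = 1, null_hours = rep(FALSE, 72), meta = NULL) {
  ch <- eeg_channels(); pairs <- channel_pairs(); bands <- eeg_bands()$band
  mk <- function(n1, d2, dn2) {
    a <- array(fill, c(n1, length(d2), 72))
    dimnames(a) <- list(NULL, d2, NULL)
    a
  }
  psd <- array(fill, c(19, 5, 72), dimnames = list(ch, bands, NULL))
  fc <- array(fill, c(171, 5, 72),
              dimnames = list(paste(pairs$a, pairs$b, sep = "_"), bands, NULL))
  bsr <- array(fill, c(19, 3, 72), dimnames = list(ch, c("5uV", "10uV", "15uV"), NULL))
  psd[, , null_hours] <- NA; fc[, , null_hours] <- NA; bsr[, , null_hours] <- NA
  structure(list(psd = psd, fc = fc, bsr = bsr, null_hours = null_hours,
                 retention = ifelse(null_hours, 0, 1), meta = meta),
            class = "feature_tensors")
}

# Planted classification design: `n_inf` informative gaussian columns among
# noise, returned with labels.
planted_design <- function(n = 120, p = 60, n_inf = 3, effect = 1.6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  y <- rep(0:1, length.out = n)
  for (j in seq_len(n_inf)) X[y == 1, j] <- X[y == 1, j] + effect
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, y = y)
}

# The large end-to-end cohort used by the acceptance suite (built lazily so
# only the tests that need it pay for it): 100 patients, 12 h each, 120 s
# hour bins at 128 Hz, default group profiles.
e2e_design <- function() {
  get_fixture("e2e_design", function() {
    cc <- cohort_config(n_patients = 100, fs = 128, duration_h = 12,
                        hour_s = 120, seed = 20230)
    coh <- generate_cohort(cc)
    cfg <- feature_config(fs_target = 128, hour_s = 120)
    tl <- lapply(coh$records, extract_patient, cfg = cfg)
    dm <- build_design_matrix(filter_patients(tl))
    list(cohort = coh, dm = dm)
  })
}
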