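# The three hourly feature tensors: Welch band power (19 x 5 x 72),
# magnitude-squared coherence over all channel pairs (171 x 5 x 72), and
# burst suppression ratio at the 5/10/15 uV thresholds (19 x 3 x 72). Hours
# failing the retention gate, and hours beyond the end of the recording, carry
# explicit NA null markers, never zeros.

#' Feature-extraction configuration
#'
#' @param fs_target standard sampling rate (Hz, default 256).
#' @param band band-pass edges for preprocessing (default c(0.5, 45)).
#' @param hour_s seconds per hour bin (default 3600).
#' @param epoch_s spectral/QC epoch length in seconds (default 2).
#' @param coh_epoch_s coherence epoch length in seconds (default 30).
#' @param coh_segments number of Welch sub-segments within one coherence epoch
#'   (default 24; the estimator's independence bias is ~1/K).
#' @param welch_seg_s Welch segment length inside a spectral epoch (default 1 s,
#'   a 1 Hz frequency grid).
#' @param p2p_max,p2p_min epoch rejection bounds in uV (defaults 300 and 1).
#' @param retention_floor minimum retained fraction per hour (default 0.30).
#' @param thresholds BSR suppression thresholds in uV (default c(5, 10, 15)).
#' @param bsr_env_s BSR envelope RMS window (s, default 0.25).
#' @param bsr_min_supp_s minimum duration of a suppressed run (s, default 0.5).
#' @param bsr_gap_s suppressed runs closer than this are merged (s, default 0.1).
#' @param n_hours length of the hourly axis (default 72).
#' @return list of class `feature_config`.
#' @export
feature_config <- function(fs_target = 256, band = c(0.5, 45), hour_s = 3600,
                           epoch_s = 2, coh_epoch_s = 30, coh_segments = 24,
                           welch_seg_s = 1, p2p_max = 300, p2p_min = 1,
                           retention_floor = 0.30,
                           thresholds = bsr_thresholds(), bsr_env_s = 0.25,
                           bsr_min_supp_s = 0.5, bsr_gap_s = 0.1,
                           n_hours = 72) {
  structure(as.list(environment()), class = "feature_config")
}

#' Hourly band power
#'
#' Arithmetic mean of the per-epoch Welch band powers over the kept 2 s epochs
#' of one hour; NA matrix if the retention gate failed.
#'
#' @param eps a rejected `epoch_set` of 2 s epochs (see [reject_epochs()]).
#' @param cfg a [feature_config()].
#' @return 19 x 5 matrix of band powers (uV^2), or all-NA if gated out.
#' @export
hourly_psd <- function(eps, cfg = feature_config()) {
  nch <- dim(eps$epochs)[1]
  out <- matrix(NA_real_, nch, 5, dimnames = list(NULL, eeg_bands()$band))
  if (!retention_gate(eps, cfg$retention_floor)) return(out)
  kept <- which(eps$keep)
  if (length(kept) == 0) return(out)
  # the mean over epochs of per-epoch Welch estimates equals the mean over all
  # (epoch, segment) periodograms, so all segments go through one FFT call
  L <- round(cfg$welch_seg_s * eps$fs)
  starts <- welch_segments(dim(eps$epochs)[2], L)
  w <- hann_window(L)
  u <- sum(w^2)
  nseg <- length(kept) * length(starts)
  big <- matrix(0, L, nch * nseg)
  col <- 0L
  for (e in kept) {
    ep <- eps$epochs[, , e, drop = TRUE]
    for (s in starts) {
      big[, col + seq_len(nch)] <- t(ep[, s:(s + L - 1L), drop = FALSE]) * w
      col <- col + nch
    }
  }
  P <- Mod(stats::mvfft(big))^2
  dim(P) <- c(L * nch, nseg)
  psd <- matrix(rowSums(P), L, nch) / (nseg * eps$fs * u)
  nfb <- floor(L / 2) + 1L
  psd <- psd[seq_len(nfb), , drop = FALSE]
  if (nfb > 2L) psd[2:(nfb - 1L), ] <- 2 * psd[2:(nfb - 1L), , drop = FALSE]
  freq <- (seq_len(nfb) - 1L) * eps$fs / L
  band_idx <- band_of_freq(freq)
  df <- eps$fs / L
  for (b in seq_len(5)) {
    sel <- which(band_idx == b)
    out[, b] <- if (length(sel) > 0) colSums(psd[sel, , drop = FALSE]) * df else 0
  }
  out
}

#' Hourly functional connectivity
#'
#' Per-pair, per-band magnitude-squared coherence averaged over the kept 30 s
#' epochs of one hour. The same peak-to-peak QC rule as for the 2 s epochs is
#' applied to the 30 s epochs; the hour is null if the retention gate fails.
#'
#' @param eps a rejected `epoch_set` of 30 s epochs.
#' @param cfg a [feature_config()].
#' @return 171 x 5 matrix of MSC values, or all-NA if gated out.
#' @export
hourly_connectivity <- function(eps, cfg = feature_config()) {
  pairs <- channel_pairs()
  out <- matrix(NA_real_, nrow(pairs), 5,
                dimnames = list(paste(pairs$a, pairs$b, sep = "_"), eeg_bands()$band))
  if (!retention_gate(eps, cfg$retention_floor)) return(out)
  kept <- which(eps$keep)
  if (length(kept) == 0) return(out)
  acc <- matrix(0, nrow(pairs), 5)
  for (e in kept) {
    acc <- acc + msc_all_pairs(eps$epochs[, , e], eps$fs, cfg$coh_segments, pairs)$band_msc
  }
  acc / length(kept)
}

# Suppression detection on one channel: RMS envelope in sliding windows,
# suppressed where the envelope is below the threshold; suppressed runs closer
# than gap_s are merged, then runs shorter than min_s are discarded.
suppressed_samples <- function(x, thr, fs, env_s = 0.25, min_s = 0.5, gap_s = 0.1,
                               env = NULL) {
  if (is.null(env)) env <- running_rms(x, max(1L, round(env_s * fs)))
  supp <- env < thr
  r <- rle(supp)
  # merge across short burst gaps
  if (length(r$lengths) > 2) {
    gap <- !r$values & r$lengths < gap_s * fs
    gap[1] <- gap[length(gap)] <- FALSE  # never merge across the edges
    r$values[gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  # drop short suppressed runs
  shrt <- r$values & r$lengths < min_s * fs
  r$values[shrt] <- FALSE
  inverse.rle(r)
}

# Centred running RMS with shrinking windows at the edges.
running_rms <- function(x, w) {
  cs <- c(0, cumsum(x^2))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Burst suppression ratio for one hour
#'
#' Per channel and threshold, the fraction of (artifact-free) time the EEG
#' amplitude envelope spends in suppression: the envelope is the RMS in
#' sliding 0.25 s windows, a suppressed run must persist >= 0.5 s, and runs
#' separated by < 0.1 s are merged. Detection runs on the continuous hour
#' signal (suppression needs continuity); epochs rejected by QC are masked out
#' of the time base. BSR is monotone non-decreasing in the threshold.
#'
#' @param hour_signal 19 x samples matrix (uV) for one hour.
#' @param cfg a [feature_config()].
#' @param keep_mask optional per-2 s-epoch logical QC mask; masked-out epochs
#'   are excluded from both numerator and denominator.
#' @param gated logical; if FALSE the hour is null (NA).
#' @return 19 x 3 matrix of BSR values in \[0, 1\] (or all-NA if `gated` is
#'   FALSE), columns named by threshold.
#' @export
bsr_hour <- function(hour_signal, cfg = feature_config(), keep_mask = NULL,
                     gated = TRUE) {
  thr <- cfg$thresholds
  nch <- nrow(hour_signal)
  out <- matrix(NA_real_, nch, length(thr),
                dimnames = list(rownames(hour_signal), paste0(thr, "uV")))
  if (!gated) return(out)
  n <- ncol(hour_signal)
  tb <- rep(TRUE, n)  # time base after artifact masking
  if (!is.null(keep_mask)) {
    L <- round(cfg$epoch_s * attr_fs(cfg))
    ep <- pmin(((seq_len(n) - 1L) %/% L) + 1L, length(keep_mask))
    tb <- keep_mask[ep]
  }
  if (!any(tb)) return(out)
  fs <- attr_fs(cfg)
  for (i in seq_len(nch)) {
    env <- running_rms(hour_signal[i, ], max(1L, round(cfg$bsr_env_s * fs)))
    for (j in seq_along(thr)) {
      supp <- suppressed_samples(hour_signal[i, ], thr[j], fs, cfg$bsr_env_s,
                                 cfg$bsr_min_supp_s, cfg$bsr_gap_s, env = env)
      out[i, j] <- sum(supp & tb) / sum(tb)
    }
  }
  out
}

attr_fs <- function(cfg) cfg$fs_target

#' Extract the full feature tensors for one patient
#'
#' Runs the ingest chain (montage mapping, filtering/resampling/average
#' reference) and, for each hour bin, epoch rejection and the three feature
#' families. Hours beyond the end of the recording, and hours failing the 30%
#' retention gate, are null (NA) and flagged in `null_hours`.
#'
#' @param rec an [eeg_recording()] (raw or standardised).
#' @param cfg a [feature_config()]; its `hour_s` is overridden by the
#'   recording's own hour length.
#' @param preprocessed set TRUE if `rec` is already standardised.
#' @return object of class `feature_tensors`: list with `psd` (19 x 5 x 72),
#'   `fc` (171 x 5 x 72), `bsr` (19 x 3 x 72), `null_hours` (logical 72),
#'   `retention` (numeric 72) and `meta`.
#' @export
extract_patient <- function(rec, cfg = feature_config(), preprocessed = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!preprocessed) {
    rec <- map_montage(rec)
    rec <- preprocess(rec, band = cfg$band, fs_target = cfg$fs_target)
  }
  cfg$hour_s <- rec$hour_s
  cfg$fs_target <- rec$fs
  ch <- eeg_channels()
  pairs <- channel_pairs()
  H <- cfg$n_hours
  psd <- array(NA_real_, c(19, 5, H), dimnames = list(ch, eeg_bands()$band, NULL))
  fc <- array(NA_real_, c(171, 5, H),
              dimnames = list(paste(pairs$a, pairs$b, sep = "_"), eeg_bands()$band, NULL))
  bsr <- array(NA_real_, c(19, 3, H),
               dimnames = list(ch, paste0(cfg$thresholds, "uV"), NULL))
  null_hours <- rep(TRUE, H)
  retention <- rep(NA_real_, H)

  blocks <- hour_blocks(rec)
  for (bn in names(blocks)) {
    h <- as.integer(bn)
    if (h < 0 || h >= H) next
    blk <- blocks[[bn]]
    brec <- eeg_recording(blk, channels = ch, fs = rec$fs, hour_s = rec$hour_s)
    e2 <- reject_epochs(make_epochs(brec, cfg$epoch_s), cfg$p2p_max, cfg$p2p_min)
    retention[h + 1L] <- e2$retention
    gate <- retention_gate(e2, cfg$retention_floor)
    if (!gate) next
    null_hours[h + 1L] <- FALSE
    psd[, , h + 1L] <- hourly_psd(e2, cfg)
    e30 <- reject_epochs(make_epochs(brec, cfg$coh_epoch_s), cfg$p2p_max, cfg$p2p_min)
    if (any(e30$keep)) fc[, , h + 1L] <- hourly_connectivity(e30, cfg)
    bsr[, , h + 1L] <- bsr_hour(blk, cfg, keep_mask = e2$keep, gated = TRUE)
  }
  structure(list(psd = psd, fc = fc, bsr = bsr, null_hours = null_hours,
                 retention = retention, meta = rec$meta),
            class = "feature_tensors")
}

#' @export
print.feature_tensors <- function(x, ...) {
  cat(sprintf("<feature_tensors> psd %s | fc %s | bsr %s | %d non-null hours\n",
              paste(dim(x$psd), collapse = "x"), paste(dim(x$fc), collapse = "x"),
              paste(dim(x$bsr), collapse = "x"), sum(!x$null_hours)))
  invisible(x)
}
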