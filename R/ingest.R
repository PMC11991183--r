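# Standardisation of raw recordings: montage mapping to the fixed 19-channel
# 10-20 set, band-pass filtering, resampling to the target rate, average
# referencing, epoching, and amplitude-based epoch rejection with the 30%
# retention gate.

# Older/newer 10-20 temporal-chain naming equivalences, applied on read.
CHANNEL_ALIASES <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Map a raw recording onto the canonical 19-channel montage
#'
#' Channel labels are matched case-insensitively, the T7/T8/P7/P8 aliases are
#' translated to the older T3/T4/T5/T6 names, rows are reordered to the fixed
#' canonical order, and extra channels (e.g. A1/A2, ECG) are dropped.
#'
#' @param raw an [eeg_recording()] with arbitrary channels.
#' @return an [eeg_recording()] with exactly the 19 canonical channels in
#'   canonical order.
#' @export
map_montage <- function(raw) {
  stopifnot(inherits(raw, "eeg_recording"))
  have <- raw$channels
  norm <- toupper(trimws(have))
  ali <- toupper(names(CHANNEL_ALIASES))
  norm[norm %in% ali] <- CHANNEL_ALIASES[match(norm[norm %in% ali], ali)]
  norm <- toupper(norm)
  want <- eeg_channels()
  pos <- match(toupper(want), norm)
  if (anyNA(pos)) {
    stop("montage error: missing channel(s) ", paste(want[is.na(pos)], collapse = ", "))
  }
  eeg_recording(raw$signal[pos, , drop = FALSE], channels = want, fs = raw$fs,
                start_hour = raw$start_hour, hour_s = raw$hour_s, meta = raw$meta)
}

#' Standardise a montage-mapped recording
#'
#' Order of operations: zero-phase Butterworth band-pass (2nd-order high-pass
#' at the lower edge, 8th-order low-pass at the upper edge; the squared
#' magnitude response of each filter — identical to a forward-backward pass —
#' is applied in the frequency domain over the whole recording), polyphase
#' resampling to the target rate, then average referencing, after which the
#' cross-channel mean is zero at every sample.
#'
#' @param rec a 19-channel [eeg_recording()] (see [map_montage()]).
#' @param band band-pass edges in Hz (default c(0.5, 45)).
#' @param fs_target output sampling rate in Hz (default 256).
#' @return standardised [eeg_recording()].
#' @export
preprocess <- function(rec, band = c(0.5, 45), fs_target = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$signal) < 10 * rec$fs) stop("recording shorter than filter warm-up (10 s)")
  fs <- rec$fs
  # low-pass must be steep: epoch rejection and band powers assume mains and
  # EMG content above 45 Hz is gone (>= 40 dB down by 60 Hz)
  lp <- signal::butter(8, band[2] / (fs / 2), type = "low")
  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  x <- zero_phase_filter(rec$signal, fs, lp, hp)
  if (fs != fs_target) {
    g <- gcd_int(round(fs_target), round(fs))
    p <- round(fs_target) / g; q <- round(fs) / g
    n_out <- floor(ncol(x) * p / q)
    y <- matrix(0, nrow(x), n_out)
    for (i in seq_len(nrow(x))) {
      r <- signal::resample(x[i, ], p, q)
      y[i, ] <- r[seq_len(n_out)]
    }
    x <- y
    fs <- fs_target
  }
  x <- sweep(x, 2, colMeans(x))  # average reference
  rownames(x) <- rec$channels
  eeg_recording(x, channels = rec$channels, fs = fs,
                start_hour = rec$start_hour, hour_s = rec$hour_s, meta = rec$meta)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Zero-phase filtering of all channels at once: |H(e^jw)|^2 of each digital
# filter (the magnitude response of a forward-backward pass) applied on the
# FFT grid of the whole recording (periodic boundary).
zero_phase_filter <- function(X, fs, ...) {
  n <- ncol(X)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  om <- 2 * pi * f / fs
  G <- rep(1, n)
  for (flt in list(...)) {
    b <- flt$b; a <- flt$a
    E <- exp(-1i * outer(om, seq_along(b) - 1))
    H <- as.vector(E %*% b) / as.vector(E %*% a)
    G <- G * Mod(H)^2
  }
  out <- Re(stats::mvfft(stats::mvfft(t(X)) * G, inverse = TRUE)) / n
  t(out)
}

#' Split a recording into non-overlapping epochs
#'
#' @param rec an [eeg_recording()].
#' @param epoch_s epoch length in seconds (2 for spectral/QC epochs, 30 for
#'   coherence epochs).
#' @return object of class `epoch_set`: list with `epochs` (channels x samples
#'   x n array), `keep` (per-epoch logical, initially all TRUE), `retention`,
#'   `epoch_s`, `fs`. Trailing samples that do not fill an epoch are
#'   discarded.
#' @export
make_epochs <- function(rec, epoch_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(epoch_s * rec$fs)
  n_ep <- floor(ncol(rec$signal) / L)
  if (n_ep == 0) {
    eps <- array(0, dim = c(nrow(rec$signal), L, 0))
  } else {
    eps <- array(rec$signal[, seq_len(n_ep * L), drop = FALSE],
                 dim = c(nrow(rec$signal), L, n_ep))
  }
  structure(list(epochs = eps, keep = rep(TRUE, n_ep), retention = 1,
                 epoch_s = epoch_s, fs = rec$fs),
            class = "epoch_set")
}

#' Reject epochs by peak-to-peak amplitude
#'
#' An epoch is kept iff its maximum peak-to-peak amplitude over channels lies
#' within \[`p2p_min`, `p2p_max`\] (boundary values kept; rejection is strict).
#' The upper bound removes high-amplitude artifacts, the lower bound removes
#' flatline stretches. The rule uses the channel maximum, so permuting
#' channels does not change the keep flags.
#'
#' @param eps an `epoch_set` from [make_epochs()].
#' @param p2p_max upper peak-to-peak bound in uV (default 300).
#' @param p2p_min lower peak-to-peak bound in uV (default 1).
#' @return the `epoch_set` with updated `keep` flags and `retention`.
#' @export
reject_epochs <- function(eps, p2p_max = 300, p2p_min = 1) {
  stopifnot(inherits(eps, "epoch_set"))
  n_ep <- dim(eps$epochs)[3]
  if (n_ep == 0) {
    eps$retention <- 0
    return(eps)
  }
  p2p <- vapply(seq_len(n_ep), function(e) {
    m <- eps$epochs[, , e, drop = FALSE]
    max(apply(m[, , 1, drop = TRUE], 1, function(r) max(r) - min(r)))
  }, numeric(1))
  eps$keep <- p2p <= p2p_max & p2p >= p2p_min
  eps$p2p <- p2p
  eps$retention <- mean(eps$keep)
  eps
}

#' Retention gate for one hour of data
#'
#' When epoch rejection leaves less than `floor` (default 30%) of the hour's
#' data, every feature of that hour is assigned a null (NA) marker downstream.
#' The boundary is kept: "less than 30%" is strict.
#'
#' @param eps an `epoch_set` with rejection applied.
#' @param floor minimum retention fraction (default 0.30).
#' @return logical: TRUE if the hour's features may be computed.
#' @export
retention_gate <- function(eps, floor = 0.30) {
  stopifnot(inherits(eps, "epoch_set"))
  eps$retention >= floor
}

# Split a standardised recording into hour blocks. Returns a list of
# channels x samples matrices, named by absolute hour index (0-based from
# ROSC); partial trailing hours are kept (the retention gate handles them).
hour_blocks <- function(rec) {
  n_hour <- round(rec$hour_s * rec$fs)
  n <- ncol(rec$signal)
  n_blocks <- ceiling(n / n_hour)
  out <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    idx <- ((i - 1L) * n_hour + 1L):min(i * n_hour, n)
    out[[i]] <- rec$signal[, idx, drop = FALSE]
  }
  names(out) <- as.character(floor(rec$start_hour) + seq_len(n_blocks) - 1L)
  out
}
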