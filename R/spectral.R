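# Spectral estimation primitives: Welch power spectral density per band and
# segment-averaged magnitude-squared coherence (MSC). These are the statistics
# the feature tensors are built from, so they are implemented here directly on
# top of the FFT rather than delegated.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# Segment start indices for Welch-style averaging: `nseg` segments of length L
# with 50% overlap tile N samples when L = floor(2N/(nseg+1)).
welch_segments <- function(n_samples, seg_len, overlap = 0.5) {
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n_samples - seg_len + 1L, by = step)
  starts
}

#' Welch band power of one epoch
#'
#' Per-channel power spectral density by Welch's method (Hann segments, 50%
#' overlap), integrated over the five canonical EEG bands. The default 1 s
#' segment length gives a 1 Hz frequency grid, and because the bands tile
#' \[0.5, 45\] Hz the five band powers sum exactly to the total power on that
#' range (Parseval consistency).
#'
#' @param epoch numeric matrix, channels x samples (uV), one analysis epoch.
#' @param fs sampling rate in Hz.
#' @param seg_s Welch segment length in seconds (default 1).
#' @param overlap fractional segment overlap (default 0.5).
#' @return matrix channels x 5 of band powers in uV^2, columns named by band.
#' @export
welch_band_power <- function(epoch, fs, seg_s = 1, overlap = 0.5) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (anyNA(epoch)) stop("NaN/NA samples in epoch; run QC before spectral estimation")
  n <- ncol(epoch)
  L <- round(seg_s * fs)
  if (n < L) stop("epoch shorter than one Welch segment")
  psd <- welch_psd(epoch, fs, L, overlap)
  band_idx <- band_of_freq(psd$freq)
  df <- fs / L
  bp <- sapply(seq_len(5), function(b) {
    sel <- which(band_idx == b)
    if (length(sel) == 0) return(rep(0, nrow(epoch)))
    colSums(psd$psd[sel, , drop = FALSE]) * df
  })
  if (nrow(epoch) == 1L) bp <- matrix(bp, nrow = 1)
  dimnames(bp) <- list(rownames(epoch), eeg_bands()$band)
  bp
}

# One-sided Welch PSD for all channels at once.
# Returns list(freq, psd = nfreq x channels, uV^2/Hz).
welch_psd <- function(epoch, fs, seg_len, overlap = 0.5) {
  w <- hann_window(seg_len)
  u <- sum(w^2)
  starts <- welch_segments(ncol(epoch), seg_len, overlap)
  nch <- nrow(epoch)
  acc <- matrix(0, seg_len, nch)
  for (s in starts) {
    seg <- t(epoch[, s:(s + seg_len - 1L), drop = FALSE]) * w
    acc <- acc + Mod(stats::mvfft(seg))^2
  }
  acc <- acc / (length(starts) * fs * u)
  nf <- floor(seg_len / 2) + 1L
  one <- acc[seq_len(nf), , drop = FALSE]
  if (nf > 2L) one[2:(nf - 1L), ] <- 2 * one[2:(nf - 1L), , drop = FALSE]
  if (seg_len %% 2 == 1L) one[nf, ] <- 2 * one[nf, ]
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = one)
}

#' Magnitude-squared coherence of a channel pair
#'
#' MSC is estimated within one epoch by splitting it into `K` Hann sub-segments
#' with 50% overlap, averaging the cross- and auto-power spectra over the
#' sub-segments, and forming |S_xy|^2 / (S_xx S_yy) per frequency bin. Band
#' values are unweighted means of the per-bin MSC over the bins inside each
#' band. Segment averaging is essential: with a single segment the estimate is
#' identically 1. The raw estimator carries the classical small-sample bias,
#' approximately (1 - C)^2 / K, which is ~1/K for independent signals.
#'
#' @param x,y numeric vectors, equal-length channel signals (typically 30 s).
#' @param fs sampling rate in Hz.
#' @param K number of Welch sub-segments (default 24).
#' @param by_band if TRUE (default) return the 5 per-band means, else the full
#'   per-frequency coherence spectrum.
#' @return named numeric vector of length 5 (bands), or a data.frame
#'   (freq, msc) when `by_band = FALSE`. NA with a warning for zero-variance
#'   input.
#' @export
msc_pair <- function(x, y, fs, K = 24, by_band = TRUE) {
  stopifnot(length(x) == length(y))
  if (var_pop(x) < .Machine$double.eps || var_pop(y) < .Machine$double.eps) {
    warning("zero-variance input: coherence undefined")
    if (by_band) return(stats::setNames(rep(NA_real_, 5), eeg_bands()$band))
    return(data.frame(freq = numeric(0), msc = numeric(0)))
  }
  X <- rbind(x, y)
  res <- msc_all_pairs(X, fs, K, pairs = data.frame(ia = 1L, ib = 2L))
  if (by_band) {
    out <- res$band_msc[1, ]
    names(out) <- eeg_bands()$band
    return(out)
  }
  data.frame(freq = res$freq, msc = res$spec_msc[, 1])
}

# MSC for a set of channel pairs in one epoch. X is channels x samples.
# Accumulates cross- and auto-spectra segment-by-segment (vectorised over all
# pairs at once). Returns list(band_msc = npair x 5, freq, spec_msc).
msc_all_pairs <- function(X, fs, K = 24, pairs = channel_pairs()) {
  n <- ncol(X)
  L <- floor(2 * n / (K + 1))
  if (L < 8) stop("epoch too short for the requested number of sub-segments")
  w <- hann_window(L)
  starts <- welch_segments(n, L)
  nf <- floor(L / 2)
  freq <- seq_len(nf) * fs / L
  npair <- nrow(pairs)
  ia <- pairs$ia; ib <- pairs$ib
  Sauto <- matrix(0, nf, nrow(X))
  Sxy <- matrix(0 + 0i, nf, npair)
  for (s in starts) {
    Fk <- stats::mvfft(t(X[, s:(s + L - 1L), drop = FALSE]) * w)[2:(nf + 1L), , drop = FALSE]
    Sauto <- Sauto + Mod(Fk)^2
    Sxy <- Sxy + Fk[, ia, drop = FALSE] * Conj(Fk[, ib, drop = FALSE])
  }
  spec <- Mod(Sxy)^2 / (Sauto[, ia, drop = FALSE] * Sauto[, ib, drop = FALSE])
  band_idx <- band_of_freq(freq)
  band_msc <- matrix(NA_real_, npair, 5, dimnames = list(NULL, eeg_bands()$band))
  for (b in seq_len(5)) {
    sel <- which(band_idx == b)
    if (length(sel) > 0) band_msc[, b] <- colMeans(spec[sel, , drop = FALSE])
  }
  list(band_msc = band_msc, freq = freq, spec_msc = spec)
}
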