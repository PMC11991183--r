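# Signal-level building blocks of the synthetic EEG generator: band-limited
# noise with exact target band power, coherent source injection with a
# closed-form coherence oracle, a two-state burst/suppression process, and
# amplitude artifacts. Everything is deterministic under a fixed seed and
# returns its ground truth, so downstream estimators can be tested against
# known values.

# Band-limited Gaussian noise via FFT-domain masking: white noise is shaped to
# zero outside [lo, hi] Hz and rescaled so its realized (population) variance
# equals `variance` exactly. The mask edges are tapered with a raised cosine
# inside the band (width `taper` Hz): a brick-wall edge would give the signal
# sinc-like long-range autocorrelation, which makes Welch sub-segments
# dependent and visibly distorts segment-averaged coherence; the taper leaves
# per-bin coherence of co-generated components untouched (all components share
# the mask, and coherence is scale-free per bin). Assumes the caller holds the
# RNG state.
band_limited_noise <- function(n, fs, lo, hi, variance, taper = 0.25) {
  if (variance < 0) stop("band power must be non-negative")
  if (variance == 0) return(numeric(n))
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  fr <- folded_freqs(n, fs)
  m <- band_mask(fr, lo, hi, taper)
  x <- Re(stats::fft(Z * m, inverse = TRUE)) / n
  v <- var_pop(x)
  if (v <= 0) stop("band [", lo, ",", hi, "] Hz contains no frequency bins at this length")
  (x - mean(x)) * sqrt(variance / v)
}

# Folded (two-sided) frequency of each FFT bin.
folded_freqs <- function(n, fs) pmin(0:(n - 1), n - (0:(n - 1))) * fs / n

# Tapered band mask on a folded frequency grid (see band_limited_noise).
band_mask <- function(fr, lo, hi, taper = 0.25) {
  w <- min(taper, (hi - lo) / 4)
  m <- numeric(length(fr))
  m[fr >= lo & fr <= hi] <- 1
  rl <- fr >= lo & fr < lo + w
  rh <- fr > hi - w & fr <= hi
  m[rl] <- 0.5 - 0.5 * cos(pi * (fr[rl] - lo) / w)
  m[rh] <- 0.5 - 0.5 * cos(pi * (hi - fr[rh]) / w)
  m
}

# One hour of all channels at once: each channel's spectrum is white noise
# shaped by the root of the summed per-band masks (scaled so each band's
# expected variance hits its target power), and each planted pair shares one
# band-limited source of variance vs, giving in-band coherence
# vs^2 / (P_a P_b) by the closed form. One FFT per channel + one per source.
# Assumes the caller holds the RNG state.
synth_hour_signal <- function(n, fs, pw, planted, fc_band_i, taper = 0.25) {
  nch <- nrow(pw)
  b <- eeg_bands()
  fr <- folded_freqs(n, fs)
  msq <- lapply(seq_len(5), function(bi) band_mask(fr, b$lo[bi], b$hi[bi], taper)^2)
  norm <- vapply(msq, function(m2) sum(m2) / n, numeric(1))
  np <- if (is.null(planted)) 0L else nrow(planted)
  nv <- pw  # per-channel in-band noise variance (source variance removed)
  if (np > 0) for (p in seq_len(np)) {
    nv[planted$ia[p], fc_band_i] <- max(pw[planted$ia[p], fc_band_i] - planted$vs[p], 0)
    nv[planted$ib[p], fc_band_i] <- max(pw[planted$ib[p], fc_band_i] - planted$vs[p], 0)
  }
  Z <- stats::mvfft(matrix(stats::rnorm(n * (nch + np)), n))
  spec <- matrix(0 + 0i, n, nch)
  for (c_i in seq_len(nch)) {
    A2 <- numeric(n)
    for (bi in seq_len(5)) {
      if (nv[c_i, bi] > 0) A2 <- A2 + msq[[bi]] * (nv[c_i, bi] / norm[bi])
    }
    spec[, c_i] <- Z[, c_i] * sqrt(A2)
  }
  if (np > 0) for (p in seq_len(np)) {
    As <- sqrt(msq[[fc_band_i]] * (planted$vs[p] / norm[fc_band_i]))
    src <- Z[, nch + p] * As
    spec[, planted$ia[p]] <- spec[, planted$ia[p]] + src
    spec[, planted$ib[p]] <- spec[, planted$ib[p]] + src
  }
  t(Re(stats::mvfft(spec, inverse = TRUE)) / n)
}

#' Synthesize one channel of band-structured EEG noise
#'
#' The signal is a sum of five independent band-limited Gaussian noise
#' processes, one per canonical band, each rescaled so its realized variance
#' equals the requested band power. A Welch band-power estimate on the output
#' therefore recovers the targets up to window leakage.
#'
#' @param band_powers numeric length-5 vector of target band powers (uV^2), in
#'   canonical band order (delta, theta, alpha, beta, gamma).
#' @param duration_s signal duration in seconds.
#' @param fs sampling rate in Hz; must exceed 90 Hz so the gamma upper edge
#'   (45 Hz) stays below Nyquist.
#' @param seed integer RNG seed.
#' @return numeric vector of `duration_s * fs` samples (uV).
#' @export
synth_channel_noise <- function(band_powers, duration_s, fs, seed = 1) {
  stopifnot(length(band_powers) == 5)
  if (any(band_powers < 0)) stop("band powers must be non-negative")
  if (fs <= 90) stop("fs must exceed 90 Hz (Nyquist above the 45 Hz gamma edge)")
  n <- round(duration_s * fs)
  b <- eeg_bands()
  with_seed(seed, {
    x <- numeric(n)
    for (i in seq_len(5)) {
      x <- x + band_limited_noise(n, fs, b$lo[i], b$hi[i], band_powers[i])
    }
    x
  })
}

#' Inject a shared band-limited source into a channel pair
#'
#' Within the chosen band, the two channels' content is replaced by
#' `x1 = s + n1` and `x2 = a*s + n2`, where `s`, `n1`, `n2` are independent
#' band-limited processes with variances `source_var`, `noise_vars[1]`,
#' `noise_vars[2]`. The expected magnitude-squared coherence inside the band is
#' the closed form
#' \deqn{C = a^2 \sigma_s^4 / ((\sigma_s^2+\sigma_1^2)(a^2\sigma_s^2+\sigma_2^2))}
#' which serves as the oracle for the coherence estimator. Content outside the
#' band is left untouched.
#'
#' @param pair_signals 2 x n matrix, the two channel signals (uV).
#' @param mixing mixing weight `a >= 0` of the source into the second channel.
#' @param source_var source variance (uV^2), > 0.
#' @param noise_vars length-2 vector of in-band noise variances (uV^2), >= 0.
#' @param band band name ("delta", ...) or numeric c(lo, hi) in Hz within
#'   \[0.5, 45\].
#' @param fs sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return list with `signals` (2 x n matrix) and `expected_msc` (the closed
#'   form above).
#' @export
inject_coherent_source <- function(pair_signals, mixing, source_var, noise_vars,
                                   band, fs, seed = 1) {
  stopifnot(is.matrix(pair_signals), nrow(pair_signals) == 2)
  if (mixing < 0) stop("mixing weight must be >= 0")
  if (source_var <= 0) stop("source variance must be > 0")
  if (any(noise_vars < 0)) stop("noise variances must be >= 0")
  edges <- band_edges(band)
  if (edges[1] < 0.5 || edges[2] > 45) stop("band outside [0.5, 45] Hz")
  n <- ncol(pair_signals)
  a <- mixing
  with_seed(seed, {
    s <- band_limited_noise(n, fs, edges[1], edges[2], source_var)
    n1 <- if (noise_vars[1] > 0) band_limited_noise(n, fs, edges[1], edges[2], noise_vars[1]) else numeric(n)
    n2 <- if (noise_vars[2] > 0) band_limited_noise(n, fs, edges[1], edges[2], noise_vars[2]) else numeric(n)
    out <- pair_signals
    out[1, ] <- remove_band(pair_signals[1, ], fs, edges) + s + n1
    out[2, ] <- remove_band(pair_signals[2, ], fs, edges) + a * s + n2
    denom <- (source_var + noise_vars[1]) * (a^2 * source_var + noise_vars[2])
    expected <- if (denom == 0) {
      if (a > 0) 1 else 0
    } else a^2 * source_var^2 / denom
    list(signals = out, expected_msc = expected)
  })
}

band_edges <- function(band) {
  if (is.character(band)) {
    b <- eeg_bands()
    i <- match(band, b$band)
    if (is.na(i)) stop("unknown band: ", band)
    c(b$lo[i], b$hi[i])
  } else {
    stopifnot(length(band) == 2, band[1] < band[2])
    as.numeric(band)
  }
}

# Zero out [lo,hi] Hz content of a signal (FFT masking).
remove_band <- function(x, fs, edges) {
  n <- length(x)
  Z <- stats::fft(x)
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) * fs / n
  Z[fr >= edges[1] & fr <= edges[2]] <- 0
  Re(stats::fft(Z, inverse = TRUE)) / n
}

#' Impose a burst/suppression process on a recording block
#'
#' An alternating two-state renewal process with exponentially distributed
#' state durations (memoryless, the simplest generative choice) is sampled and
#' applied to all channels simultaneously: during suppression the signal is
#' scaled by `supp_scale` so its amplitude falls below the lowest BSR
#' threshold. The suppression mean duration is solved from the requested
#' long-run occupancy: E\[supp\] = p / (1 - p) * E\[burst\].
#'
#' @param signal channels x samples matrix (uV).
#' @param occupancy target long-run suppression time fraction p in \[0, 1\].
#' @param mean_burst_s mean burst duration in seconds (default 2).
#' @param mean_supp_s mean suppression duration; if NULL (default), solved from
#'   `occupancy`.
#' @param supp_scale amplitude scale during suppression, must be < 1
#'   (default 0.02).
#' @param fs sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return list with `signal` (modified matrix) and `state` (logical per
#'   sample, TRUE while suppressed) as ground truth.
#' @export
inject_burst_suppression <- function(signal, occupancy, mean_burst_s = 2,
                                     mean_supp_s = NULL, supp_scale = 0.02,
                                     fs, seed = 1) {
  stopifnot(is.matrix(signal))
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0, 1]")
  if (mean_burst_s <= 0) stop("mean burst duration must be > 0")
  if (supp_scale >= 1) stop("supp_scale must be < 1: suppression would not be suppressed")
  n <- ncol(signal)
  if (occupancy == 0) return(list(signal = signal, state = rep(FALSE, n)))
  if (occupancy == 1) {
    return(list(signal = signal * supp_scale, state = rep(TRUE, n)))
  }
  if (is.null(mean_supp_s)) mean_supp_s <- occupancy / (1 - occupancy) * mean_burst_s
  if (mean_supp_s <= 0) stop("mean suppression duration must be > 0")
  state <- with_seed(seed, {
    st <- logical(0)
    # start in a state drawn from the stationary occupancy
    cur <- stats::runif(1) < occupancy
    while (length(st) < n) {
      dur <- stats::rexp(1, rate = 1 / (if (cur) mean_supp_s else mean_burst_s))
      st <- c(st, rep(cur, max(1L, round(dur * fs))))
      cur <- !cur
    }
    st[seq_len(n)]
  })
  out <- signal
  out[, state] <- out[, state] * supp_scale
  list(signal = out, state = state)
}

#' Inject amplitude artifacts into a recording block
#'
#' Random 2 s-aligned segments are replaced either by a high-amplitude
#' excursion (a 250 uV sinusoid, peak-to-peak 500 uV > the 300 uV rejection
#' bound) or by a near-flat stretch (all-zero, peak-to-peak < 1 uV). Each 2 s
#' epoch is independently affected with probability `high_amp_rate` /
#' `flat_rate`. The per-epoch artifact mask is returned as ground truth.
#'
#' @param signal channels x samples matrix (uV).
#' @param high_amp_rate per-epoch probability of a high-amplitude artifact.
#' @param flat_rate per-epoch probability of a flat artifact.
#' @param fs sampling rate (Hz).
#' @param seed integer RNG seed.
#' @param epoch_s artifact alignment length in seconds (default 2).
#' @return list with `signal` and `artifact_mask`, a character vector per
#'   epoch in {"none", "high", "flat"}.
#' @export
inject_artifacts <- function(signal, high_amp_rate, flat_rate, fs, seed = 1,
                             epoch_s = 2) {
  stopifnot(is.matrix(signal))
  if (high_amp_rate < 0 || flat_rate < 0) stop("artifact rates must be >= 0")
  L <- round(epoch_s * fs)
  n_ep <- floor(ncol(signal) / L)
  mask <- rep("none", n_ep)
  if (n_ep == 0 || (high_amp_rate == 0 && flat_rate == 0)) {
    return(list(signal = signal, artifact_mask = mask))
  }
  out <- signal
  with_seed(seed, {
    u <- stats::runif(n_ep)
    for (e in seq_len(n_ep)) {
      idx <- ((e - 1L) * L + 1L):(e * L)
      if (u[e] < high_amp_rate) {
        mask[e] <- "high"
        art <- 250 * sin(2 * pi * 2 * (seq_len(L) - 1) / fs)
        out[, idx] <- matrix(art, nrow(signal), L, byrow = TRUE)
      } else if (u[e] < high_amp_rate + flat_rate) {
        mask[e] <- "flat"
        out[, idx] <- 0
      }
    }
  })
  list(signal = out, artifact_mask = mask)
}
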