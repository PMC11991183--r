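# Canonical definitions shared by every module: the 19-channel 10-20 montage,
# the five EEG frequency bands, the 171 unordered channel pairs, and the four
# aggregation periods after return of spontaneous circulation (ROSC).

#' The 19-channel 10-20 electrode set
#'
#' Fixed channel order used by every standardised recording and feature tensor.
#'
#' @return Character vector of 19 channel labels.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' Canonical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz. Bands are
#' half-open on the right except gamma, which includes its 45 Hz upper edge,
#' so the five bands tile \[0.5, 45\] Hz exactly.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(0.5, 4, 8, 13, 30),
    hi   = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Assign frequency grid bins to bands
#'
#' @param freqs numeric vector of frequencies (Hz).
#' @return integer vector, the band index (1..5) of each frequency, NA outside
#'   \[0.5, 45\].
#' @keywords internal
band_of_freq <- function(freqs) {
  b <- eeg_bands()
  idx <- rep(NA_integer_, length(freqs))
  for (i in seq_len(nrow(b))) {
    inb <- freqs >= b$lo[i] & freqs < b$hi[i]
    if (b$band[i] == "gamma") inb <- freqs >= b$lo[i] & freqs <= b$hi[i]
    idx[inb] <- i
  }
  idx
}

#' All unordered channel pairs
#'
#' The (19*18)/2 = 171 pairs, enumerated in fixed lexicographic order over the
#' canonical channel list (first channel always precedes the second in that
#' order). This ordering defines the rows of the coherence tensor and the
#' `FC_{chA}_{chB}_...` feature names.
#'
#' @return data.frame with columns `a`, `b` (channel names) and `ia`, `ib`
#'   (indices into [eeg_channels()]).
#' @export
channel_pairs <- function() {
  ch <- eeg_channels()
  n <- length(ch)
  ia <- ib <- integer(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    k <- k + 1L
    ia[k] <- i; ib[k] <- j
  }
  data.frame(a = ch[ia], b = ch[ib], ia = ia, ib = ib, stringsAsFactors = FALSE)
}

#' Aggregation periods after ROSC
#'
#' T1 = hours \[0,12), T2 = \[12,24), T3 = \[24,48), T4 = \[48,72). Disjoint and
#' covering the 72 h analysis window.
#'
#' @return data.frame with columns `period`, `from`, `to` (half-open hours).
#' @export
eeg_periods <- function() {
  data.frame(
    period = c("T1", "T2", "T3", "T4"),
    from = c(0L, 12L, 24L, 48L),
    to   = c(12L, 24L, 48L, 72L),
    stringsAsFactors = FALSE
  )
}

#' Burst suppression ratio thresholds (uV)
#' @return numeric vector c(5, 10, 15).
#' @export
bsr_thresholds <- function() c(5, 10, 15)

#' Frequency class of a band
#'
#' Delta and theta are "low", beta and gamma "high"; alpha is kept as its own
#' class because its role in the short/long-distance dichotomy is ambiguous.
#'
#' @param band character vector of band names.
#' @return character vector in {"low", "high", "alpha"}.
#' @export
classify_band <- function(band) {
  stopifnot(all(band %in% eeg_bands()$band))
  out <- ifelse(band %in% c("delta", "theta"), "low",
         ifelse(band %in% c("beta", "gamma"), "high", "alpha"))
  out
}
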