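# Recording and metadata containers, and minimal WFDB-compatible on-disk IO
# (format-16 header + signal pairs with a plain-text clinical sidecar, the
# layout used by the I-CARE continuous-EEG releases). No WFDB reader exists in
# the installed R stack, so the subset needed here is implemented directly.

#' Construct a multichannel EEG recording
#'
#' @param signal channels x samples numeric matrix, in microvolts.
#' @param channels character vector of channel labels (one per row).
#' @param fs sampling rate in Hz.
#' @param start_hour offset of the first sample from ROSC, in hours.
#' @param hour_s seconds of signal per hour bin (3600 for real data; synthetic
#'   cohorts may compress this).
#' @param meta optional [patient_meta()].
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, channels, fs, start_hour = 0, hour_s = 3600,
                          meta = NULL) {
  stopifnot(is.matrix(signal), nrow(signal) == length(channels), fs > 0)
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  structure(list(signal = signal, channels = channels, fs = fs,
                 start_hour = start_hour, hour_s = hour_s, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.2f h from ROSC, %g s/hour bin)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              x$start_hour, x$hour_s))
  invisible(x)
}

#' Patient clinical metadata
#'
#' The outcome label is derived centrally here: good iff CPC is 1 or 2, poor
#' for CPC 3-5. Missing optional fields are kept as NA, never defaulted.
#'
#' @param id patient identifier.
#' @param hospital hospital id.
#' @param age years; `sex` "Male"/"Female"; `rosc` minutes to return of
#'   spontaneous circulation; `ohca` out-of-hospital arrest flag; `shockable`
#'   shockable-rhythm flag; `ttm` targeted temperature management code
#'   (33/36/0); `cpc` Cerebral Performance Category 1-5.
#' @param sex,rosc,ohca,shockable,ttm,cpc see above; any may be NA.
#' @return object of class `patient_meta` with derived `$label`.
#' @export
patient_meta <- function(id, hospital = NA, age = NA, sex = NA, rosc = NA,
                         ohca = NA, shockable = NA, ttm = NA, cpc = NA) {
  if (!is.na(cpc) && !(cpc %in% 1:5)) stop("CPC must be in 1..5")
  structure(list(id = id, hospital = hospital, age = age, sex = sex,
                 rosc = rosc, ohca = ohca, shockable = shockable, ttm = ttm,
                 cpc = cpc, label = cpc_to_label(cpc)),
            class = "patient_meta")
}

#' Map a CPC score to the binary outcome label
#'
#' CPC 1-2 are good (favourable) outcomes; CPC 3-5 are poor.
#'
#' @param cpc integer vector of CPC scores (NA allowed).
#' @return character vector "good"/"poor" (NA where CPC is NA).
#' @export
cpc_to_label <- function(cpc) {
  ifelse(is.na(cpc), NA_character_, ifelse(cpc %in% c(1, 2), "good", "poor"))
}

WFDB_GAIN <- 32  # ADC units per uV: +/-1023 uV range, 0.03 uV resolution

#' Write a recording as a WFDB-style record
#'
#' Emits `<path>.hea` (text header), `<path>.dat` (interleaved little-endian
#' 16-bit samples at a fixed gain) and, when metadata is attached, `<path>.txt`
#' with I-CARE-style `Key: value` lines (Age, Sex, ROSC, OHCA, Shockable
#' Rhythm, TTM, CPC, Hospital).
#'
#' @param rec an [eeg_recording()].
#' @param path output path without extension.
#' @return invisibly, `path`.
#' @export
write_record <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  name <- basename(path)
  nch <- nrow(rec$signal); ns <- ncol(rec$signal)
  hea <- c(sprintf("%s %d %g %d", name, nch, rec$fs, ns),
           sprintf("%s.dat 16 %d(0)/uV 16 0 0 0 0 %s", name, WFDB_GAIN, rec$channels),
           sprintf("#start_hour %g", rec$start_hour),
           sprintf("#hour_s %g", rec$hour_s))
  writeLines(hea, paste0(path, ".hea"))
  q <- round(rec$signal * WFDB_GAIN)
  q <- pmin(pmax(q, -32767), 32767)
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.integer(q), con, size = 2, endian = "little")
  close(con)
  if (!is.null(rec$meta)) {
    m <- rec$meta
    lines <- c(paste("Patient:", m$id),
               if (!is.na(m$hospital)) paste("Hospital:", m$hospital),
               if (!is.na(m$age)) paste("Age:", m$age),
               if (!is.na(m$sex)) paste("Sex:", m$sex),
               if (!is.na(m$rosc)) paste("ROSC:", m$rosc),
               if (!is.na(m$ohca)) paste("OHCA:", ifelse(m$ohca, "True", "False")),
               if (!is.na(m$shockable)) paste("Shockable Rhythm:",
                                              ifelse(m$shockable, "True", "False")),
               if (!is.na(m$ttm)) paste("TTM:", m$ttm),
               if (!is.na(m$cpc)) paste("CPC:", m$cpc))
    writeLines(lines, paste0(path, ".txt"))
  }
  invisible(path)
}

#' Read a WFDB-style record with its metadata sidecar
#'
#' Inverse of [write_record()]: parses the header, decodes the 16-bit signal
#' back to microvolts using the per-record gain, and reads the `Key: value`
#' sidecar if present. Missing optional metadata fields are returned as NA.
#'
#' @param path record path without extension.
#' @return list with `recording` (an [eeg_recording()]) and `meta`
#'   (a [patient_meta()], or NULL if no sidecar exists).
#' @export
read_record <- function(path) {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("cannot read record header: ", hea_path)
  lines <- readLines(hea_path)
  comments <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#")]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nch <- as.integer(top[2]); fs <- as.numeric(top[3]); ns <- as.integer(top[4])
  sig_lines <- lines[1 + seq_len(nch)]
  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", f[3])))
    list(gain = gain, label = f[length(f)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  gains <- vapply(sigs, `[[`, numeric(1), "gain")
  labels <- vapply(sigs, `[[`, character(1), "label")
  grab <- function(key, default) {
    m <- grep(paste0("^#", key, " "), comments, value = TRUE)
    if (length(m) == 0) default else as.numeric(sub(paste0("^#", key, " "), "", m[1]))
  }
  start_hour <- grab("start_hour", 0)
  hour_s <- grab("hour_s", 3600)
  dat_path <- paste0(path, ".dat")
  if (!file.exists(dat_path)) stop("cannot read signal file: ", dat_path)
  raw <- readBin(dat_path, integer(), n = nch * ns, size = 2,
                 endian = "little", signed = TRUE)
  sig <- matrix(as.numeric(raw), nrow = nch) / gains
  rownames(sig) <- labels
  meta <- NULL
  txt_path <- paste0(path, ".txt")
  if (file.exists(txt_path)) meta <- read_meta_sidecar(txt_path)
  rec <- eeg_recording(sig, channels = labels, fs = fs,
                       start_hour = start_hour, hour_s = hour_s, meta = meta)
  list(recording = rec, meta = meta)
}

read_meta_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (l in lines) {
    parts <- strsplit(l, ":\\s*")[[1]]
    if (length(parts) >= 2) kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = ":"))
  }
  as_flag <- function(v) if (is.null(v)) NA else tolower(v) %in% c("true", "1", "yes")
  as_num <- function(v) if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  patient_meta(
    id = kv[["Patient"]] %||% basename(path),
    hospital = as_num(kv[["Hospital"]]),
    age = as_num(kv[["Age"]]),
    sex = kv[["Sex"]] %||% NA_character_,
    rosc = as_num(kv[["ROSC"]]),
    ohca = as_flag(kv[["OHCA"]]),
    shockable = as_flag(kv[["Shockable Rhythm"]]),
    ttm = as_num(kv[["TTM"]]),
    cpc = as_num(kv[["CPC"]])
  )
}
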