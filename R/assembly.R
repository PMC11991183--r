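# Aggregation of hourly tensors into the four post-ROSC periods, the named
# 4028-dimensional EEG feature vector plus clinical covariates, the >= 5 h
# patient filter, and leakage-safe z-score normalisation.

#' Names of the 4028 EEG features
#'
#' For each period T1..T4: 95 PSD features (19 channels x 5 bands), 855
#' connectivity features (171 pairs x 5 bands) and 57 BSR features (19
#' channels x 3 thresholds), named `PSD_{ch}_{band}_T{n}`,
#' `FC_{chA}_{chB}_{band}_T{n}` and `BSR_{ch}_{thr}mV_T{n}`. The total is
#' 4 x (95 + 855 + 57) = 4028; the count is asserted at build time.
#'
#' @return character vector of length 4028.
#' @export
eeg_feature_names <- function() {
  ch <- eeg_channels()
  bands <- eeg_bands()$band
  pairs <- channel_pairs()
  thr <- bsr_thresholds()
  out <- character(0)
  for (p in eeg_periods()$period) {
    psd <- as.vector(t(outer(ch, bands, function(c_, b_) paste0("PSD_", c_, "_", b_))))
    fcn <- as.vector(t(outer(seq_len(nrow(pairs)), bands, function(i, b_)
      paste0("FC_", pairs$a[i], "_", pairs$b[i], "_", b_))))
    bsn <- as.vector(t(outer(ch, thr, function(c_, t_) paste0("BSR_", c_, "_", t_, "mV"))))
    out <- c(out, paste0(psd, "_", p), paste0(fcn, "_", p), paste0(bsn, "_", p))
  }
  stopifnot(length(out) == 4028, !anyDuplicated(out))
  out
}

clinical_feature_names <- function() c("age", "sex", "shockable", "ohca", "rosc", "ttm")

#' Aggregate hourly tensors into the period feature vector
#'
#' Each period feature is the mean of the corresponding hourly value over the
#' period's non-null hours; a period with no non-null hours yields NA for all
#' its features. Aggregation commutes with constant shifts.
#'
#' @param tensors a `feature_tensors` object from [extract_patient()].
#' @return named numeric vector of length 4028 (see [eeg_feature_names()]).
#' @export
aggregate_periods <- function(tensors) {
  stopifnot(inherits(tensors, "feature_tensors"))
  per <- eeg_periods()
  out <- numeric(0)
  for (i in seq_len(nrow(per))) {
    hrs <- (per$from[i] + 1L):per$to[i]
    ok <- hrs[!tensors$null_hours[hrs]]
    block_mean <- function(a) {
      if (length(ok) == 0) return(rep(NA_real_, dim(a)[1] * dim(a)[2]))
      m <- apply(a[, , ok, drop = FALSE], c(1, 2), mean)
      as.vector(t(m))  # row-major: feature blocks iterate bands within channel
    }
    out <- c(out, block_mean(tensors$psd), block_mean(tensors$fc),
             block_mean(tensors$bsr))
  }
  names(out) <- eeg_feature_names()
  out
}

#' Encode clinical covariates as numeric features
#'
#' Sex is a male indicator; OHCA and shockable rhythm are 0/1 flags; TTM keeps
#' its categorical code (33/36/0). Missing fields stay NA.
#'
#' @param meta a [patient_meta()].
#' @return named numeric vector (age, sex, shockable, ohca, rosc, ttm).
#' @export
clinical_features <- function(meta) {
  as_num <- function(v) if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  c(age = as_num(meta$age),
    sex = if (is.null(meta$sex) || is.na(meta$sex)) NA_real_ else as.numeric(meta$sex == "Male"),
    shockable = as_num(meta$shockable),
    ohca = as_num(meta$ohca),
    rosc = as_num(meta$rosc),
    ttm = as_num(meta$ttm))
}

#' Filter out patients with insufficient usable EEG
#'
#' Patients with fewer than `min_hours` non-null hours are removed (strictly
#' "less than": a patient with exactly `min_hours` usable hours is kept).
#'
#' @param tensor_list list of `feature_tensors`, one per patient.
#' @param min_hours minimum usable hours (default 5).
#' @return the filtered list; removed patient ids are attached as attribute
#'   `removed` and reported via message.
#' @export
filter_patients <- function(tensor_list, min_hours = 5) {
  usable <- vapply(tensor_list, function(t) sum(!t$null_hours), numeric(1))
  drop <- usable < min_hours
  if (any(drop)) {
    ids <- names(tensor_list)[drop] %||% which(drop)
    message("filter_patients: removing ", sum(drop), " patient(s) with < ",
            min_hours, " usable hours: ", paste(ids, collapse = ", "))
  }
  out <- tensor_list[!drop]
  attr(out, "removed") <- names(tensor_list)[drop]
  out
}

#' Build the cohort design matrix
#'
#' Assembles one row per patient: the 4028 EEG period features followed by the
#' clinical covariates. The positive class (y = 1) is poor outcome, matching
#' the framing in which a false positive is a false prediction of an adverse
#' outcome.
#'
#' @param tensor_list list of `feature_tensors` (each carrying `meta`).
#' @return list with `X` (patients x 4034 matrix), `y` (0/1 integer, 1 =
#'   poor), `groups` (hospital ids), `names` (column names), `ids`.
#' @export
build_design_matrix <- function(tensor_list) {
  stopifnot(length(tensor_list) > 0)
  nm <- c(eeg_feature_names(), clinical_feature_names())
  rows <- lapply(tensor_list, function(t) {
    c(aggregate_periods(t), clinical_features(t$meta))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- nm
  metas <- lapply(tensor_list, `[[`, "meta")
  cpc <- vapply(metas, function(m) as.numeric(m$cpc), numeric(1))
  if (anyNA(cpc)) stop("labelling error: CPC missing for some patients")
  y <- as.integer(cpc_to_label(cpc) == "poor")
  groups <- vapply(metas, function(m) as.numeric(m$hospital), numeric(1))
  ids <- vapply(metas, function(m) as.character(m$id), character(1))
  rownames(X) <- ids
  list(X = X, y = y, groups = groups, names = nm, ids = ids)
}

#' Fit a z-score normalizer on training rows
#'
#' Per-feature mean and overall (population) standard deviation, learned on
#' the training rows only: z = (x - mu) / sigma. Constant features (sigma = 0)
#' are flagged and emitted as 0 when applied. Missing values are ignored when
#' fitting and pass through as missing when applied.
#'
#' @param train_matrix training rows x features matrix.
#' @return object of class `normalizer` with `mu`, `sigma`, `constant`.
#' @export
fit_normalizer <- function(train_matrix) {
  mu <- apply(train_matrix, 2, function(col) mean(col, na.rm = TRUE))
  sigma <- apply(train_matrix, 2, sd_pop)
  mu[is.nan(mu)] <- 0  # all-missing column
  constant <- is.na(sigma) | sigma == 0
  sigma[constant] <- 1
  structure(list(mu = mu, sigma = sigma, constant = constant),
            class = "normalizer")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param norm a [fit_normalizer()] result.
#' @param matrix rows x features matrix with the same columns as the training
#'   matrix.
#' @param invert if TRUE, undo the transform (z -> x).
#' @return transformed matrix; constant features are 0 in the forward
#'   direction.
#' @export
apply_normalizer <- function(norm, matrix, invert = FALSE) {
  stopifnot(inherits(norm, "normalizer"), ncol(matrix) == length(norm$mu))
  if (!invert) {
    z <- sweep(sweep(matrix, 2, norm$mu), 2, norm$sigma, "/")
    z[, norm$constant] <- 0
    z
  } else {
    sweep(sweep(matrix, 2, norm$sigma, "*"), 2, norm$mu, "+")
  }
}

# Median imputation fitted on training rows (for classifiers that cannot
# ingest missing values); tree ensembles receive native NA markers instead.
fit_imputer <- function(train_matrix) {
  med <- apply(train_matrix, 2, function(col) stats::median(col, na.rm = TRUE))
  med[is.na(med)] <- 0
  structure(list(median = med), class = "imputer")
}

apply_imputer <- function(imp, matrix) {
  for (j in seq_len(ncol(matrix))) {
    nas <- is.na(matrix[, j])
    if (any(nas)) matrix[nas, j] <- imp$median[j]
  }
  matrix
}
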