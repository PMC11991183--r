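# Group-contrast timecourse analysis (per-feature, per-hour two-sample tests
# between the good and poor outcome groups) and the temporal-validity
# experiment: models trained on single periods, period unions and
# element-wise period differences.

#' Per-hour group contrasts of a feature family
#'
#' For every (feature, hour) cell, a Welch two-sample t-test compares the
#' non-null patient values between the good and poor groups. No multiple-
#' testing correction is applied by default; Benjamini-Hochberg adjusted
#' p-values are added when `adjust = TRUE`. Hours with fewer than
#' `min_per_group` patients in either group are flagged untested.
#'
#' @param values 3-dimensional array features x hours x patients (hourly
#'   feature values, NA for null hours). Use [timecourse_values()] to build
#'   it from per-patient tensors.
#' @param labels per-patient "good"/"poor".
#' @param min_per_group minimum patients per group per hour (default 3).
#' @param adjust add BH-adjusted p-values (default FALSE).
#' @param pooled use the pooled-variance (classical) t statistic instead of
#'   Welch (default FALSE).
#' @return data.frame with one row per (feature, hour): group means,
#'   difference (poor - good), t statistic, degrees of freedom, p-value,
#'   per-group n, `tested` flag.
#' @export
group_timecourse <- function(values, labels, min_per_group = 3,
                             adjust = FALSE, pooled = FALSE) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(labels))
  good <- which(labels == "good"); poor <- which(labels == "poor")
  if (length(good) == 0 || length(poor) == 0) stop("both groups must be non-empty")
  nf <- dim(values)[1]; nh <- dim(values)[2]
  feat_names <- dimnames(values)[[1]] %||% paste0("feature", seq_len(nf))

  stats_of <- function(idx) {
    sub <- values[, , idx, drop = FALSE]
    n <- apply(!is.na(sub), c(1, 2), sum)
    m <- apply(sub, c(1, 2), function(v) mean(v, na.rm = TRUE))
    v <- apply(sub, c(1, 2), function(v) stats::var(v, na.rm = TRUE))
    list(n = n, mean = m, var = v)
  }
  g <- stats_of(good); p <- stats_of(poor)
  diff <- p$mean - g$mean
  if (pooled) {
    df <- g$n + p$n - 2
    sp2 <- ((g$n - 1) * g$var + (p$n - 1) * p$var) / df
    se <- sqrt(sp2 * (1 / g$n + 1 / p$n))
  } else {
    se <- sqrt(g$var / g$n + p$var / p$n)
    df <- (g$var / g$n + p$var / p$n)^2 /
      ((g$var / g$n)^2 / (g$n - 1) + (p$var / p$n)^2 / (p$n - 1))
  }
  tstat <- diff / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  tested <- g$n >= min_per_group & p$n >= min_per_group & is.finite(tstat)
  pval[!tested] <- NA; tstat[!tested] <- NA
  out <- data.frame(
    feature = rep(feat_names, nh),
    hour = rep(seq_len(nh) - 1L, each = nf),
    mean_good = as.vector(g$mean), mean_poor = as.vector(p$mean),
    diff = as.vector(diff), t = as.vector(tstat), df = as.vector(df),
    p = as.vector(pval), n_good = as.vector(g$n), n_poor = as.vector(p$n),
    tested = as.vector(tested), stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Stack one feature family of a tensor list into a timecourse array
#'
#' @param tensor_list list of `feature_tensors` (one per patient).
#' @param family "psd", "fc" or "bsr".
#' @return array (features x hours x patients) with feature names
#'   `{row}_{col}` (e.g. `Cz_alpha`, `Fp1_O1_delta`, `Cz_15uV`).
#' @export
timecourse_values <- function(tensor_list, family = c("psd", "fc", "bsr")) {
  family <- match.arg(family)
  a1 <- tensor_list[[1]][[family]]
  d <- dim(a1)
  nf <- d[1] * d[2]
  out <- array(NA_real_, c(nf, d[3], length(tensor_list)))
  fn <- as.vector(outer(dimnames(a1)[[1]], dimnames(a1)[[2]], paste, sep = "_"))
  dimnames(out) <- list(fn, NULL, names(tensor_list))
  for (i in seq_along(tensor_list)) {
    a <- tensor_list[[i]][[family]]
    out[, , i] <- matrix(a, nf, d[3])
  }
  out
}

PERIOD_SPECS <- c("T1", "T2", "T3", "T4", "T1~2", "T2~3", "T3~4",
                  "T2-1", "T3-2", "T4-3", "Tall")

#' Build a period-restricted design matrix
#'
#' Specs: single periods ("T3"), unions ("T3~4" = T3 and T4 blocks side by
#' side, "Tall" = all four), and element-wise differences ("T4-3" = each T4
#' EEG feature minus its T3 counterpart, named `D_{base}_T4m3`; missing if
#' either side is missing). Clinical covariates are retained in every spec.
#'
#' @param X full design matrix with canonical column names.
#' @param spec one of "T1".."T4", "T1~2", "T2~3", "T3~4", "T2-1", "T3-2",
#'   "T4-3", "Tall".
#' @return the column-subset (or difference) matrix.
#' @export
build_period_design <- function(X, spec) {
  nm <- colnames(X)
  clinical <- nm[!grepl("_T[1-4]$", nm)]
  period_cols <- function(p) nm[grepl(paste0("_", p, "$"), nm)]
  if (spec == "Tall") {
    return(X)
  }
  if (grepl("^T[1-4]$", spec)) {
    keep <- c(period_cols(spec), clinical)
    return(X[, keep, drop = FALSE])
  }
  if (grepl("^T[1-4]~[1-4]$", spec)) {
    lo <- as.integer(substr(spec, 2, 2)); hi <- as.integer(substr(spec, 4, 4))
    stopifnot(lo < hi)
    keep <- c(unlist(lapply(lo:hi, function(i) period_cols(paste0("T", i)))), clinical)
    return(X[, keep, drop = FALSE])
  }
  if (grepl("^T[1-4]-[1-4]$", spec)) {
    later <- as.integer(substr(spec, 2, 2)); earlier <- as.integer(substr(spec, 4, 4))
    stopifnot(later > earlier)
    lc <- period_cols(paste0("T", later))
    base <- sub(paste0("_T", later, "$"), "", lc)
    ec <- paste0(base, "_T", earlier)
    stopifnot(all(ec %in% nm))
    D <- X[, lc, drop = FALSE] - X[, ec, drop = FALSE]
    colnames(D) <- paste0("D_", base, "_T", later, "m", earlier)
    return(cbind(D, X[, clinical, drop = FALSE]))
  }
  stop("unknown period spec: ", spec)
}

#' Temporal-validity experiment over period designs
#'
#' Cross-validates the classifier on each period-restricted design and
#' tabulates the mean challenge score, AUROC, AUPRC and F1 per spec.
#'
#' @param X,y full design matrix and labels.
#' @param specs character vector of period specs (see
#'   [build_period_design()]).
#' @param clf a [classifier_spec()].
#' @param folds,seed CV settings.
#' @return list with `table` (metrics x specs data.frame) and `cv` (named
#'   list of `cv_result`s).
#' @export
run_period_experiments <- function(X, y, specs, clf, folds = 5, seed = 1) {
  cvs <- list()
  for (s in specs) {
    Xs <- build_period_design(X, s)
    cvs[[s]] <- run_cv(Xs, y, clf, NULL, folds = folds, seed = seed)
  }
  metrics <- c("challenge_score", "auroc", "auprc", "f1")
  tab <- as.data.frame(lapply(cvs, function(cv) unname(cv$mean[metrics])))
  names(tab) <- specs
  rownames(tab) <- metrics
  list(table = tab, cv = cvs)
}
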