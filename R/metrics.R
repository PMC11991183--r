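# Evaluation metrics: the challenge score (maximum TPR subject to FPR <= 0.05),
# AUROC, AUPRC, F1, and per-hospital (leave-one-hospital-out) evaluation.
# The positive class is poor outcome throughout: a false positive is a false
# prediction of an adverse outcome, which is why its rate is capped.

#' True positive rate at a capped false positive rate
#'
#' Enumerates all achievable decision thresholds (midpoints between sorted
#' unique scores, plus sentinels; tied scores share a threshold) and returns
#' the maximum TPR among thresholds with FPR <= `fpr_cap` (inclusive cap). If
#' no threshold other than predict-all-negative satisfies the cap, the score
#' is 0. Invariant under strictly monotone transforms of the scores.
#'
#' @param y_true 0/1 vector (1 = positive = poor outcome).
#' @param score numeric scores, higher = more likely positive.
#' @param fpr_cap false-positive-rate cap (default 0.05).
#' @return list with `score` (the capped TPR) and `threshold` (a score
#'   threshold achieving it; predictions are `score >= threshold`).
#' @export
challenge_score <- function(y_true, score, fpr_cap = 0.05) {
  y <- as.integer(y_true)
  if (length(unique(y)) < 2) stop("challenge score undefined: single-class input")
  stopifnot(length(y) == length(score), all(y %in% c(0L, 1L)))
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  u <- sort(unique(score), decreasing = TRUE)
  thr <- c(Inf, u)  # predicting with t = Inf labels everything negative
  best_tpr <- 0
  best_thr <- Inf
  for (t in thr) {
    pred <- score >= t
    fp <- sum(pred & y == 0L)
    if (fp / nneg <= fpr_cap) {
      tpr <- sum(pred & y == 1L) / npos
      if (tpr > best_tpr) {
        best_tpr <- tpr
        best_thr <- t
      }
    }
  }
  list(score = best_tpr, threshold = best_thr)
}

#' Per-hospital challenge score from precomputed scores
#'
#' Splits the evaluation by hospital and computes the capped TPR within each.
#' Hospitals whose held-out set contains a single class are reported as NA
#' ("undefined") with a warning and excluded from the mean.
#'
#' @param y_true 0/1 labels; `score` numeric scores; `hospital_ids` grouping.
#' @param score,hospital_ids see above.
#' @param fpr_cap cap (default 0.05).
#' @return list with `per_hospital` (named numeric) and `mean`.
#' @export
grouped_challenge_score <- function(y_true, score, hospital_ids, fpr_cap = 0.05) {
  hs <- sort(unique(hospital_ids))
  per <- stats::setNames(rep(NA_real_, length(hs)), as.character(hs))
  for (h in hs) {
    idx <- hospital_ids == h
    if (length(unique(y_true[idx])) < 2) {
      warning("hospital ", h, ": single-class held-out set, challenge score undefined")
      next
    }
    per[as.character(h)] <- challenge_score(y_true[idx], score[idx], fpr_cap)$score
  }
  list(per_hospital = per, mean = mean(per, na.rm = TRUE))
}

#' Area under the ROC curve
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted 1/2 (rank statistic form).
#'
#' @param y_true 0/1 labels; `score` numeric scores.
#' @param score see above.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(y_true, score) {
  y <- as.integer(y_true)
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0 || nneg == 0) stop("AUROC undefined: single-class input")
  r <- rank(score)
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free step summation over achievable thresholds (tied scores
#' share a threshold): AP = sum over threshold steps of
#' (recall gain) x (precision at that threshold).
#'
#' @param y_true 0/1 labels; `score` numeric scores.
#' @param score see above.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(y_true, score) {
  y <- as.integer(y_true)
  npos <- sum(y == 1L)
  if (npos == 0 || npos == length(y)) stop("AUPRC undefined: single-class input")
  ord <- order(score, decreasing = TRUE)
  ys <- y[ord]; ss <- score[ord]
  cum_tp <- cumsum(ys)
  cum_pp <- seq_along(ys)
  # keep only the last index of each tied-score block
  last <- which(c(diff(ss) != 0, TRUE))
  prec <- cum_tp[last] / cum_pp[last]
  rec <- cum_tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Precision, recall and F1 from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R). When no sample is
#' predicted positive (TP+FP = 0), precision is reported as 0 with
#' `undefined_precision = TRUE`; F1 is 0 whenever P + R = 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (`tn` optional, unused).
#' @return list with `precision`, `recall`, `f1`, `undefined_precision`.
#' @export
f1_from_counts <- function(tp, fp, fn, tn = NA) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  undef <- (tp + fp) == 0
  p <- if (undef) 0 else tp / (tp + fp)
  r <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, undefined_precision = undef)
}

#' Full evaluation report for one set of scores
#'
#' Challenge score (capped TPR) with its threshold, AUROC, AUPRC, and the
#' confusion counts / precision / recall / F1 at the challenge threshold.
#'
#' @param y_true 0/1 labels; `score` numeric scores; `fpr_cap` cap.
#' @param score,fpr_cap see above.
#' @param hospital_ids optional grouping; adds a per-hospital breakdown.
#' @return object of class `score_report`.
#' @export
score_report <- function(y_true, score, fpr_cap = 0.05, hospital_ids = NULL) {
  cs <- challenge_score(y_true, score, fpr_cap)
  pred <- score >= cs$threshold
  y <- as.integer(y_true)
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L); tn <- sum(!pred & y == 0L)
  f <- f1_from_counts(tp, fp, fn, tn)
  rep <- list(challenge_score = cs$score, threshold = cs$threshold,
              auroc = auroc(y_true, score), auprc = auprc(y_true, score),
              precision = f$precision, recall = f$recall, f1 = f$f1,
              counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
  if (!is.null(hospital_ids)) {
    rep$per_hospital <- grouped_challenge_score(y_true, score, hospital_ids, fpr_cap)
  }
  structure(rep, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> challenge %.3f | AUROC %.3f | AUPRC %.3f | F1 %.3f\n",
              x$challenge_score, x$auroc, x$auprc, x$f1))
  invisible(x)
}
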