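# Additive (SHAP) attribution of the fitted classifier and its aggregation by
# the feature categories used to read the models: feature family (PSD / FC /
# BSR / clinical), electrode-distance class (short = adjacent electrodes in
# the 10-20 layout, long otherwise), frequency class (low = delta/theta,
# high = beta/gamma, alpha separate) and post-ROSC period.

#' Electrode adjacency graph of the 19-channel 10-20 montage
#'
#' Short-distance connections are those between adjacent electrode positions;
#' everything else is long-distance. The adjacency list ships as a data file
#' (`extdata/montage_adjacency.csv`) so it can be audited or replaced; the
#' default list connects each electrode to its immediate neighbours along and
#' across the standard 10-20 chains (every channel has at least two
#' neighbours, and the relation is symmetric).
#'
#' @param path optional path to an alternative two-column (a, b) CSV.
#' @return data.frame with columns `a`, `b`.
#' @export
electrode_graph <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_adjacency.csv", package = "qeegprog")
  }
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  ch <- eeg_channels()
  stopifnot(all(g$a %in% ch), all(g$b %in% ch))
  deg <- table(c(g$a, g$b))
  stopifnot(all(deg >= 2))
  g
}

#' Distance class of a channel pair
#'
#' @param chA,chB channel names in the 19-channel montage.
#' @param graph adjacency data.frame (default [electrode_graph()]).
#' @return "short" if the electrodes are adjacent, else "long". Vectorised.
#' @export
classify_pair <- function(chA, chB, graph = electrode_graph()) {
  ch <- eeg_channels()
  stopifnot(all(chA %in% ch), all(chB %in% ch))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  adj <- key(graph$a, graph$b)
  ifelse(key(chA, chB) %in% adj, "short", "long")
}

#' Annotate features by name
#'
#' Parses the canonical feature names into family, channels, band, period,
#' BSR threshold, distance class (FC only) and frequency class.
#'
#' @param names character vector of feature names.
#' @param graph electrode adjacency (default [electrode_graph()]).
#' @return data.frame, one row per feature.
#' @export
annotate_features <- function(names, graph = electrode_graph()) {
  n <- length(names)
  out <- data.frame(feature = names, family = "clinical",
                    ch_a = NA_character_, ch_b = NA_character_,
                    band = NA_character_, period = NA_character_,
                    threshold = NA_real_, distance_class = "n/a",
                    band_class = "n/a", stringsAsFactors = FALSE)
  psd <- grepl("^PSD_[^_]+_[^_]+_T[1-4]$", names)
  fc <- grepl("^FC_[^_]+_[^_]+_[^_]+_T[1-4]$", names)
  bsr <- grepl("^BSR_[^_]+_[0-9]+mV_T[1-4]$", names)
  split_parts <- strsplit(names, "_")
  for (i in which(psd)) {
    p <- split_parts[[i]]
    out$family[i] <- "PSD"; out$ch_a[i] <- p[2]; out$band[i] <- p[3]
    out$period[i] <- p[4]
  }
  for (i in which(fc)) {
    p <- split_parts[[i]]
    out$family[i] <- "FC"; out$ch_a[i] <- p[2]; out$ch_b[i] <- p[3]
    out$band[i] <- p[4]; out$period[i] <- p[5]
  }
  for (i in which(bsr)) {
    p <- split_parts[[i]]
    out$family[i] <- "BSR"; out$ch_a[i] <- p[2]
    out$threshold[i] <- as.numeric(sub("mV$", "", p[3]))
    out$period[i] <- p[4]
  }
  has_band <- !is.na(out$band)
  out$band_class[has_band] <- classify_band(out$band[has_band])
  isfc <- out$family == "FC"
  if (any(isfc)) {
    out$distance_class[isfc] <- classify_pair(out$ch_a[isfc], out$ch_b[isfc], graph)
  }
  out
}

#' Per-sample additive feature attributions
#'
#' For gradient-boosted models the exact tree-path (TreeSHAP) attributions
#' are used; for any other scorer a fixed-seed permutation-sampling Shapley
#' estimate is computed against the feature-wise median background. Per
#' sample, base value + sum of attributions equals the model output margin
#' (exactly for tree models, in expectation for the sampled fallback).
#'
#' @param model a `qeeg_model` from [fit_classifier()].
#' @param X rows x features matrix (same preprocessing view the model was
#'   fitted on).
#' @param n_perm permutations for the sampling fallback (default 64).
#' @param seed seed for the sampling fallback.
#' @return object of class `attribution_table`: list with `phi` (rows x
#'   features), `base` (per-sample base value), `X`, and `annotations`.
#' @export
attribute <- function(model, X, n_perm = 64, seed = 1) {
  stopifnot(inherits(model, "qeeg_model"))
  nms <- model$feature_names %||% colnames(X)
  if (model$kind %in% c("gbdt_a", "gbdt_b", "gbdt_c")) {
    Xn <- X
    colnames(Xn) <- colnames_xgb(ncol(X))
    contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(Xn, missing = NA),
                              predcontrib = TRUE)
    phi <- contrib[, seq_len(ncol(X)), drop = FALSE]
    base <- contrib[, ncol(contrib)]
  } else {
    sc <- sampling_shap(function(M) predict_score(model, M), X, n_perm, seed)
    phi <- sc$phi; base <- sc$base
  }
  colnames(phi) <- nms
  structure(list(phi = phi, base = base, X = X,
                 annotations = annotate_features(nms)),
            class = "attribution_table")
}

# Monte-Carlo permutation Shapley values against the median background row.
sampling_shap <- function(score_fun, X, n_perm = 64, seed = 1) {
  p <- ncol(X); n <- nrow(X)
  bg <- apply(X, 2, function(col) stats::median(col, na.rm = TRUE))
  phi <- matrix(0, n, p)
  base <- rep(as.numeric(score_fun(matrix(bg, 1, p,
                                          dimnames = list(NULL, colnames(X))))), n)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      cur <- matrix(bg, n, p, byrow = TRUE, dimnames = list(NULL, colnames(X)))
      prev_s <- as.numeric(score_fun(cur))
      for (j in ord) {
        cur[, j] <- X[, j]
        s <- as.numeric(score_fun(cur))
        phi[, j] <- phi[, j] + (s - prev_s)
        prev_s <- s
      }
    }
  })
  list(phi = phi / n_perm, base = base)
}

#' Direction tendency of a feature
#'
#' Whether high values of a feature push the model toward the poor outcome.
#' A feature whose attributions sit essentially at zero — mean |attribution|
#' below `min_share` of the largest feature's — is indeterminate (the
#' "distributed around zero" case). Otherwise the tendency is the sign of the
#' Spearman rank correlation between feature value and attribution, with a
#' `dead_zone` around zero.
#'
#' @param attribs an `attribution_table`.
#' @param feature feature name(s); default all.
#' @param dead_zone correlation dead zone (default 0.1).
#' @param min_share minimum mean-|attribution| share relative to the largest
#'   feature for a tendency call (default 0.05).
#' @return data.frame with feature, rho, tendency.
#' @export
direction_tendency <- function(attribs, feature = NULL, dead_zone = 0.1,
                               min_share = 0.05) {
  stopifnot(inherits(attribs, "attribution_table"))
  if (nrow(attribs$X) < 20) stop("need >= 20 samples for a tendency estimate")
  feats <- feature %||% colnames(attribs$phi)
  scale_ref <- max(colMeans(abs(attribs$phi)), 0)
  rho <- vapply(feats, function(f) {
    x <- attribs$X[, f]; s <- attribs$phi[, f]
    ok <- !is.na(x) & !is.na(s)
    if (sum(ok) < 20 || stats::sd(x[ok]) == 0 || stats::sd(s[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], s[ok], method = "spearman")
  }, numeric(1))
  negligible <- colMeans(abs(attribs$phi[, feats, drop = FALSE])) <
    min_share * scale_ref
  tendency <- ifelse(is.na(rho) | negligible, "indeterminate",
              ifelse(rho > dead_zone, "positive",
              ifelse(rho < -dead_zone, "negative", "indeterminate")))
  data.frame(feature = feats, rho = rho, tendency = tendency,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attribution summary by feature category
#'
#' Aggregates the attribution table over a category partition (default the
#' feature family): signed mean attribution, mean absolute attribution, and
#' each category's share of the total absolute attribution (shares sum to 1).
#'
#' @param attribs an `attribution_table`.
#' @param by character vector of annotation columns to group by (default
#'   "family"; e.g. `c("distance_class", "band_class")` for the connectivity
#'   dichotomy).
#' @return data.frame with the grouping columns and `mean_attr`,
#'   `mean_abs_attr`, `share`, sorted by decreasing share.
#' @export
category_summary <- function(attribs, by = "family") {
  stopifnot(inherits(attribs, "attribution_table"))
  ann <- attribs$annotations
  stopifnot(all(by %in% names(ann)))
  phi <- attribs$phi
  key <- do.call(paste, c(ann[by], sep = "|"))
  total_abs <- sum(abs(phi))
  groups <- split(seq_len(ncol(phi)), key)
  rows <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    block <- phi[, cols, drop = FALSE]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    df <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(df) <- by
    df$mean_attr <- mean(block)
    df$mean_abs_attr <- mean(abs(block))
    df$share <- if (total_abs > 0) sum(abs(block)) / total_abs else NA_real_
    df
  })
  out <- do.call(rbind, rows)
  out[order(-out$share), , drop = FALSE]
}

#' Top features by mean absolute attribution
#'
#' @param attribs an `attribution_table`.
#' @param k number of features (default 40).
#' @return data.frame: feature, mean_abs_attr, annotations, tendency.
#' @export
top_attributions <- function(attribs, k = 40) {
  stopifnot(inherits(attribs, "attribution_table"))
  mabs <- colMeans(abs(attribs$phi))
  ord <- order(-mabs)[seq_len(min(k, length(mabs)))]
  out <- attribs$annotations[ord, , drop = FALSE]
  out$mean_abs_attr <- mabs[ord]
  rownames(out) <- NULL
  out
}
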