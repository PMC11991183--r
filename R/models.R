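# Feature-selection x classification harness: five selector kinds, seven
# classifier kinds, stratified five-fold cross-validation with in-fold
# normalisation and selection (no leakage), a selector x classifier x k grid,
# the 1..100 feature-count sweep with the < 0.01 AUROC threshold rule, and
# leave-one-hospital-out evaluation.

SELECTOR_KINDS <- c("l1_linear_svm", "random_forest_importance",
                    "gbdt_importance_a", "gbdt_importance_b", "gbdt_importance_c")
CLASSIFIER_KINDS <- c("random_forest", "knn", "logistic", "svm_rbf",
                      "gbdt_a", "gbdt_b", "gbdt_c")

#' Feature-selector specification
#'
#' Kinds: `l1_linear_svm` (sparse L1-penalised linear model; features ranked
#' by entry order along the regularisation path), `random_forest_importance`
#' (impurity importance), and `gbdt_importance_a/b/c` (gain importance of the
#' three gradient-boosting configurations, see [classifier_spec()]).
#'
#' @param kind one of the selector kinds above.
#' @param k number of features to keep (>= 1).
#' @param seed integer seed.
#' @param params optional list of engine parameters.
#' @return object of class `selector_spec`.
#' @export
selector_spec <- function(kind, k, seed = 1, params = list()) {
  kind <- match.arg(kind, SELECTOR_KINDS)
  if (k < 1) stop("k must be >= 1")
  structure(list(kind = kind, k = as.integer(k), seed = seed, params = params),
            class = "selector_spec")
}

#' Classifier specification
#'
#' Kinds: `random_forest`, `knn`, `logistic`, `svm_rbf`, and three
#' gradient-boosted-tree configurations: `gbdt_a` (depth-wise growth),
#' `gbdt_b` (leaf-wise "lossguide" growth), `gbdt_c` (shallow
#' symmetric-style trees; the primary classifier). All produce a continuous
#' score oriented so that higher means more likely poor outcome.
#'
#' @param kind one of the classifier kinds above.
#' @param seed integer seed.
#' @param params optional list overriding engine defaults.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind, seed = 1, params = list()) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  structure(list(kind = kind, seed = seed, params = params),
            class = "classifier_spec")
}

# Does this kind consume the dense (imputed + normalised) view of the data?
needs_dense <- function(kind) {
  kind %in% c("knn", "logistic", "svm_rbf", "random_forest", "l1_linear_svm",
              "random_forest_importance")
}

#' Rank and select features on training data
#'
#' Returns the indices of the top-k features. Ranking is by |coefficient|
#' entry order along the L1 path for the linear selector, or by importance
#' score for the tree selectors; ties are broken by column order. The linear
#' selector expects imputed, normalised inputs; tree selectors accept raw
#' (missing-aware) inputs.
#'
#' @param spec a [selector_spec()].
#' @param X_train training rows x features matrix.
#' @param y_train 0/1 labels.
#' @return integer vector of length `k` (top features, best first), with the
#'   full ranking as attribute `ranking`.
#' @export
select_features <- function(spec, X_train, y_train) {
  stopifnot(inherits(spec, "selector_spec"))
  p <- ncol(X_train)
  if (spec$k > p) stop("k exceeds the number of available features")
  imp <- feature_importance(spec, X_train, y_train)
  ranking <- order(-imp, seq_len(p))
  out <- ranking[seq_len(spec$k)]
  attr(out, "ranking") <- ranking
  attr(out, "importance") <- imp
  out
}

feature_importance <- function(spec, X, y) {
  kind <- spec$kind
  p <- ncol(X)
  if (kind == "l1_linear_svm") {
    Xi <- X
    if (anyNA(Xi)) Xi <- apply_imputer(fit_imputer(Xi), Xi)
    fit <- with_seed(spec$seed,
      glmnet::glmnet(Xi, factor(y), family = "binomial", alpha = 1,
                     standardize = FALSE, nlambda = 100))
    beta <- as.matrix(fit$beta)  # p x nlambda
    entry <- apply(beta != 0, 1, function(nz) if (any(nz)) which(nz)[1] else Inf)
    # earlier path entry = more important; |coef| at the densest fit breaks ties
    tail_coef <- abs(beta[, ncol(beta)])
    -entry + 1e-9 * tail_coef / (max(tail_coef) + 1e-12)
  } else if (kind == "random_forest_importance") {
    Xi <- X
    if (anyNA(Xi)) Xi <- apply_imputer(fit_imputer(Xi), Xi)
    colnames(Xi) <- paste0("f", seq_len(p))
    fit <- ranger::ranger(x = Xi, y = factor(y), importance = "impurity",
                          num.trees = spec$params$num_trees %||% 500,
                          seed = spec$seed, num.threads = 1)
    unname(fit$variable.importance)
  } else {
    variant <- sub("gbdt_importance_", "", kind)
    booster <- fit_gbdt(X, y, variant, spec$seed, spec$params)
    im <- xgboost::xgb.importance(model = booster)
    imp <- stats::setNames(rep(0, p), colnames_xgb(p))
    imp[im$Feature] <- im$Gain
    unname(imp)
  }
}

colnames_xgb <- function(p) paste0("f", seq_len(p))

gbdt_params <- function(variant) {
  switch(variant,
    a = list(max_depth = 6, eta = 0.1, subsample = 0.9, colsample_bytree = 0.8,
             grow_policy = "depthwise", tree_method = "hist", nrounds = 200),
    b = list(max_depth = 0, max_leaves = 31, eta = 0.1, subsample = 0.9,
             colsample_bytree = 0.8, grow_policy = "lossguide",
             tree_method = "hist", nrounds = 200),
    c = list(max_depth = 4, eta = 0.08, subsample = 1, colsample_bytree = 1,
             grow_policy = "depthwise", tree_method = "hist", nrounds = 300),
    stop("unknown gbdt variant: ", variant))
}

fit_gbdt <- function(X, y, variant, seed, overrides = list()) {
  pp <- gbdt_params(variant)
  pp[names(overrides)] <- overrides
  nrounds <- pp$nrounds
  pp$nrounds <- NULL
  Xn <- X
  colnames(Xn) <- colnames_xgb(ncol(X))
  dtrain <- xgboost::xgb.DMatrix(Xn, label = y, missing = NA)
  params <- c(pp, list(objective = "binary:logistic", nthread = 1,
                       seed = seed, eval_metric = "logloss"))
  with_seed(seed, xgboost::xgb.train(params = params, data = dtrain,
                                     nrounds = nrounds, verbose = 0))
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()].
#' @param X training matrix (imputed/normalised for dense kinds, raw with NA
#'   for the gradient-boosting kinds).
#' @param y 0/1 labels (1 = poor outcome).
#' @return model object of class `qeeg_model`; score with [predict_score()].
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  kind <- spec$kind
  fit <- switch(kind,
    random_forest = with_seed(spec$seed, {
      Xi <- X; colnames(Xi) <- colnames_xgb(ncol(X))
      ranger::ranger(x = Xi, y = factor(y, levels = c(0, 1)),
                     probability = TRUE,
                     num.trees = spec$params$num_trees %||% 500,
                     seed = spec$seed, num.threads = 1)
    }),
    knn = list(X = X, y = y, k = spec$params$k %||% 5),
    logistic = with_seed(spec$seed, {
      df <- data.frame(y = y, X)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    }),
    svm_rbf = with_seed(spec$seed, {
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                 probability = TRUE)
    }),
    gbdt_a = fit_gbdt(X, y, "a", spec$seed, spec$params),
    gbdt_b = fit_gbdt(X, y, "b", spec$seed, spec$params),
    gbdt_c = fit_gbdt(X, y, "c", spec$seed, spec$params))
  structure(list(kind = kind, fit = fit, spec = spec, p = ncol(X),
                 feature_names = colnames(X)),
            class = c(paste0("qeeg_model_", kind), "qeeg_model"))
}

#' Score new samples with a fitted classifier
#'
#' @param model a `qeeg_model` from [fit_classifier()].
#' @param X matrix with the same columns as at fit time.
#' @return numeric scores, higher = more likely poor outcome.
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "qeeg_model"))
  kind <- model$kind
  if (kind == "random_forest") {
    Xi <- X; colnames(Xi) <- colnames_xgb(ncol(X))
    as.numeric(stats::predict(model$fit, data = Xi)$predictions[, "1"])
  } else if (kind == "knn") {
    pr <- class::knn(train = model$fit$X, test = X,
                     cl = factor(model$fit$y, levels = c(0, 1)),
                     k = model$fit$k, prob = TRUE)
    p <- attr(pr, "prob")
    ifelse(pr == "1", p, 1 - p)
  } else if (kind == "logistic") {
    as.numeric(stats::predict(model$fit, newdata = data.frame(X),
                              type = "response"))
  } else if (kind == "svm_rbf") {
    pr <- stats::predict(model$fit, X, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, "1"])
  } else {
    Xn <- X
    colnames(Xn) <- colnames_xgb(ncol(X))
    stats::predict(model$fit, xgboost::xgb.DMatrix(Xn, missing = NA))
  }
}

# Stratified fold assignment: patients of each class are shuffled and dealt
# round-robin, guaranteeing both classes in every training fold when each
# class has >= folds members... (validated by run_cv).
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated evaluation of a selector/classifier pipeline
#'
#' Stratified k-fold CV at the patient level. Inside each fold, and on the
#' training rows only: the imputer and z-score normalizer are fitted, the
#' selector (if any) ranks features, and the classifier is fitted on the
#' top-k; the held-out rows are then transformed with the fold's fitted state
#' and scored. Nothing fitted ever sees held-out rows.
#'
#' @param X rows x features matrix; `y` 0/1 labels (1 = poor).
#' @param y,folds,seed see above / below.
#' @param clf a [classifier_spec()].
#' @param selector a [selector_spec()] or NULL for no selection.
#' @param fpr_cap challenge-score cap (default 0.05).
#' @return object of class `cv_result`: per-fold `score_report`s, fold
#'   assignment, selected feature names per fold, and `mean`/`sd` per metric.
#' @export
run_cv <- function(X, y, clf, selector = NULL, folds = 5, seed = 1,
                   fpr_cap = 0.05) {
  stopifnot(inherits(clf, "classifier_spec"))
  y <- as.integer(y)
  fold <- stratified_folds(y, folds, seed)
  for (f in seq_len(folds)) {
    if (length(unique(y[fold != f])) < 2) stop("stratification error: single-class training fold")
  }
  reports <- vector("list", folds)
  sel_names <- vector("list", folds)
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    prep <- fold_fit(X[tr, , drop = FALSE], y[tr], clf, selector)
    sel_names[[f]] <- prep$selected_names
    scores[te] <- fold_score(prep, X[te, , drop = FALSE])
    reports[[f]] <- score_report(y[te], scores[te], fpr_cap)
  }
  metrics <- c("challenge_score", "auroc", "auprc", "f1")
  tab <- sapply(metrics, function(m) vapply(reports, `[[`, numeric(1), m))
  structure(list(fold = fold, reports = reports, selected = sel_names,
                 scores = scores,
                 mean = colMeans(tab), sd = apply(tab, 2, stats::sd)),
            class = "cv_result")
}

# Fit the full in-fold pipeline (imputer/normalizer -> selector -> classifier)
# on training rows; returns a scoring closure state.
fold_fit <- function(Xtr, ytr, clf, selector = NULL, sel_idx_override = NULL) {
  imp <- fit_imputer(Xtr)
  Xd <- apply_imputer(imp, Xtr)
  norm <- fit_normalizer(Xd)
  Xn <- apply_normalizer(norm, Xd)
  sel_idx <- seq_len(ncol(Xtr))
  if (!is.null(sel_idx_override)) {
    sel_idx <- sel_idx_override
  } else if (!is.null(selector)) {
    Xsel <- if (needs_dense(selector$kind)) Xn else Xtr
    sel_idx <- select_features(selector, Xsel, ytr)
  }
  Xfit <- if (needs_dense(clf$kind)) Xn[, sel_idx, drop = FALSE]
          else Xtr[, sel_idx, drop = FALSE]
  model <- fit_classifier(clf, Xfit, ytr)
  list(model = model, imputer = imp, normalizer = norm, sel_idx = sel_idx,
       dense = needs_dense(clf$kind),
       selected_names = colnames(Xtr)[sel_idx])
}

fold_score <- function(prep, Xte) {
  Xd <- if (prep$dense) {
    apply_normalizer(prep$normalizer, apply_imputer(prep$imputer, Xte))
  } else Xte
  predict_score(prep$model, Xd[, prep$sel_idx, drop = FALSE])
}

#' Selector x classifier x k grid evaluation
#'
#' Runs [run_cv()] for every combination and tabulates the mean challenge
#' score and AUROC, one row per (selector, classifier, k) cell. `"none"` is a
#' valid selector kind (direct classification on the full feature matrix; `k`
#' is ignored for it).
#'
#' @param X,y design matrix and labels.
#' @param selectors character vector of selector kinds (may include "none").
#' @param classifiers character vector of classifier kinds.
#' @param k_values integer vector of feature counts (default c(25, 75)).
#' @param folds,seed CV settings.
#' @return data.frame with columns selector, classifier, k, challenge_score,
#'   auroc.
#' @export
grid_search <- function(X, y, selectors, classifiers, k_values = c(25, 75),
                        folds = 5, seed = 1) {
  rows <- list()
  for (sk in selectors) {
    kv <- if (sk == "none") NA_integer_ else k_values
    for (ck in classifiers) for (k in kv) {
      sel <- if (sk == "none") NULL else selector_spec(sk, k, seed = seed)
      cv <- run_cv(X, y, classifier_spec(ck, seed = seed), sel,
                   folds = folds, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        selector = sk, classifier = ck, k = k,
        challenge_score = unname(cv$mean["challenge_score"]),
        auroc = unname(cv$mean["auroc"]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Feature-count sweep with the < 0.01 AUROC rule
#'
#' For each k in `k_range`, evaluates the selector/classifier pipeline by CV
#' (the selector ranking is computed once per fold and truncated to each k)
#' and finds the minimal k whose mean AUROC is within 0.01 of the
#' full-feature baseline with the same classifier; the analogous minimal k
#' for the challenge score is also reported.
#'
#' @param X,y design matrix and labels.
#' @param selector_kind selector kind for the ranking.
#' @param clf a [classifier_spec()].
#' @param k_range integer vector of feature counts (default 1:100).
#' @param folds,seed,fpr_cap CV settings.
#' @return list with `curve` (data.frame k, auroc, challenge_score),
#'   `baseline` (named numeric), `min_k_auroc`, `min_k_challenge`.
#' @export
feature_sweep <- function(X, y, selector_kind, clf, k_range = 1:100,
                          folds = 5, seed = 1, fpr_cap = 0.05) {
  y <- as.integer(y)
  base_cv <- run_cv(X, y, clf, NULL, folds = folds, seed = seed, fpr_cap = fpr_cap)
  fold <- base_cv$fold
  k_range <- sort(unique(pmin(k_range, ncol(X))))
  kmax <- max(k_range)
  # per-fold ranking computed once; the top-k prefix is k-independent
  rankings <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    spec <- selector_spec(selector_kind, kmax, seed = seed)
    Xtr <- X[tr, , drop = FALSE]
    Xsel <- if (needs_dense(selector_kind)) {
      apply_normalizer(fit_normalizer(apply_imputer(fit_imputer(Xtr), Xtr)),
                       apply_imputer(fit_imputer(Xtr), Xtr))
    } else Xtr
    rankings[[f]] <- attr(select_features(spec, Xsel, y[tr]), "ranking")
  }
  curve <- data.frame(k = k_range, auroc = NA_real_, challenge_score = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    au <- ch <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      idx <- rankings[[f]][seq_len(k)]
      prep <- fold_fit(X[tr, , drop = FALSE], y[tr], clf, sel_idx_override = idx)
      sc <- fold_score(prep, X[te, , drop = FALSE])
      rep <- score_report(y[te], sc, fpr_cap)
      au[f] <- rep$auroc; ch[f] <- rep$challenge_score
    }
    curve$auroc[i] <- mean(au)
    curve$challenge_score[i] <- mean(ch)
  }
  min_k <- function(col, base) {
    ok <- which(base - curve[[col]] < 0.01)
    if (length(ok) == 0) NA_integer_ else curve$k[min(ok)]
  }
  list(curve = curve,
       baseline = c(auroc = unname(base_cv$mean["auroc"]),
                    challenge_score = unname(base_cv$mean["challenge_score"])),
       min_k_auroc = min_k("auroc", base_cv$mean["auroc"]),
       min_k_challenge = min_k("challenge_score", base_cv$mean["challenge_score"]))
}

#' Leave-one-hospital-out evaluation
#'
#' Each hospital in turn is held out; the pipeline is fitted on the remaining
#' hospitals and the held-out patients are scored. The challenge score is
#' computed within each held-out hospital (NA with a warning if it has a
#' single class) and averaged.
#'
#' @param X,y design matrix and labels.
#' @param hospital hospital id per patient.
#' @param clf a [classifier_spec()]; `selector` optional [selector_spec()].
#' @param selector,fpr_cap see above.
#' @return list with `per_hospital` (named numeric), `mean`, and the pooled
#'   out-of-sample `scores`.
#' @export
loho_cv <- function(X, y, hospital, clf, selector = NULL, fpr_cap = 0.05) {
  y <- as.integer(y)
  hs <- sort(unique(hospital))
  per <- stats::setNames(rep(NA_real_, length(hs)), as.character(hs))
  scores <- rep(NA_real_, length(y))
  for (h in hs) {
    te <- hospital == h; tr <- !te
    prep <- fold_fit(X[tr, , drop = FALSE], y[tr], clf, selector)
    scores[te] <- fold_score(prep, X[te, , drop = FALSE])
    if (length(unique(y[te])) < 2) {
      warning("hospital ", h, ": single-class held-out set, challenge score undefined")
      next
    }
    per[as.character(h)] <- challenge_score(y[te], scores[te], fpr_cap)$score
  }
  list(per_hospital = per, mean = mean(per, na.rm = TRUE), scores = scores)
}
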