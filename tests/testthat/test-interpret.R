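# Additive attributions, the electrode-distance and band dichotomies, and
# category aggregation.

test_that("the shipped electrode adjacency is symmetric with degree >= 2", {
  g <- electrode_graph()
  expect_true(all(g$a %in% eeg_channels()) && all(g$b %in% eeg_channels()))
  deg <- table(c(g$a, g$b))
  expect_length(deg, 19)
  expect_true(all(deg >= 2))
  # no duplicate edges in either orientation
  key <- paste(pmin(g$a, g$b), pmax(g$a, g$b))
  expect_false(anyDuplicated(key) > 0)
})

test_that("pair distance classes match the montage geometry", {
  expect_equal(classify_pair("Fp1", "Fp2"), "short")
  expect_equal(classify_pair("Cz", "Pz"), "short")
  expect_equal(classify_pair("Pz", "Cz"), "short")  # orientation-free
  expect_equal(classify_pair("F4", "O1"), "long")
  expect_equal(classify_pair("Fp1", "T6"), "long")
  expect_error(classify_pair("Fp1", "XX"))
})

test_that("bands map to the low/high/alpha classes", {
  expect_equal(classify_band(c("delta", "theta")), c("low", "low"))
  expect_equal(classify_band(c("beta", "gamma")), c("high", "high"))
  expect_equal(classify_band("alpha"), "alpha")
  expect_error(classify_band("mu"))
})

test_that("feature names parse into complete annotations", {
  ann <- annotate_features(c("PSD_Cz_alpha_T1", "FC_Cz_Pz_alpha_T2",
                             "BSR_F7_15mV_T3", "FC_F4_O1_delta_T4", "age"))
  expect_equal(ann$family, c("PSD", "FC", "BSR", "FC", "clinical"))
  expect_equal(ann$period, c("T1", "T2", "T3", "T4", NA))
  expect_equal(ann$distance_class, c("n/a", "short", "n/a", "long", "n/a"))
  expect_equal(ann$band_class, c("alpha", "alpha", "n/a", "low", "n/a"))
  expect_equal(ann$threshold[3], 15)
})

test_that("tree attributions are additive and sign-consistent on a stump", {
  set.seed(71)
  n <- 60
  X <- cbind(FC_Cz_Pz_alpha_T2 = rnorm(n), PSD_Cz_alpha_T1 = rnorm(n))
  y <- as.integer(X[, 1] > 0)  # single-feature decision
  model <- fit_classifier(classifier_spec("gbdt_c", seed = 1,
                                          params = list(max_depth = 1, nrounds = 30)),
                          X, y)
  at <- attribute(model, X)
  margin <- qlogis(pmin(pmax(predict_score(model, X), 1e-12), 1 - 1e-12))
  expect_lt(max(abs(rowSums(at$phi) + at$base - margin)), 1e-5)
  # attribution sign tracks the split side of the driving feature
  expect_true(all(sign(at$phi[X[, 1] > 0.3, 1]) == 1))
  expect_true(all(sign(at$phi[X[, 1] < -0.3, 1]) == -1))
  expect_true(all(abs(at$phi[, 2]) <= 1e-8))
})

test_that("the sampling fallback approximates additivity for a linear scorer", {
  set.seed(72)
  n <- 30
  X <- matrix(rnorm(3 * n), n, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(1, -2, 0.5)
  fake <- structure(list(kind = "logistic",
                         fit = NULL, feature_names = colnames(X)),
                    class = c("qeeg_model_logistic", "qeeg_model"))
  sc <- qeegprog:::sampling_shap(function(M) as.numeric(M %*% beta), X,
                                 n_perm = 16, seed = 1)
  # for a linear model the Shapley value is beta_j (x_j - median_j), exactly
  med <- apply(X, 2, stats::median)
  want <- sweep(X, 2, med) %*% diag(beta)
  expect_lt(max(abs(sc$phi - want)), 1e-8)
  expect_equal(unname(rowSums(sc$phi) + sc$base),
               as.numeric(X %*% beta), tolerance = 1e-8)
})

test_that("direction tendencies recover planted monotone effects", {
  set.seed(73)
  n <- 200
  driver <- rnorm(n)
  y <- as.integer(driver + rnorm(n, sd = 0.4) > 0)
  shallow <- classifier_spec("gbdt_c", seed = 2,
                             params = list(max_depth = 2, nrounds = 60))
  Xp <- cbind(FC_F3_P4_delta_T1 = driver, PSD_O1_delta_T2 = rnorm(n))
  atp <- attribute(fit_classifier(shallow, Xp, y), Xp)
  expect_equal(direction_tendency(atp)$tendency[1], "positive")
  # the negated driver acquires the opposite tendency
  Xn <- cbind(FC_F7_T6_delta_T1 = -driver, PSD_O1_delta_T2 = rnorm(n))
  atn <- attribute(fit_classifier(shallow, Xn, y), Xn)
  expect_equal(direction_tendency(atn)$tendency[1], "negative")
  # a pure-noise feature among others is mostly indeterminate across refits
  noise_calls <- vapply(1:10, function(s) {
    Xs <- cbind(FC_F3_P4_delta_T1 = driver,
                matrix(rnorm(10 * n), n,
                       dimnames = list(NULL, paste0("PSD_O", 1:10, "_delta_T2"))))
    m <- fit_classifier(classifier_spec("gbdt_c", seed = s,
                                        params = list(max_depth = 2, nrounds = 30)),
                        Xs, y)
    direction_tendency(attribute(m, Xs))$tendency[2]
  }, character(1))
  expect_gte(mean(noise_calls == "indeterminate"), 0.9)
})

test_that("category shares form a partition of unity", {
  set.seed(74)
  n <- 40
  X <- cbind(FC_Cz_Pz_alpha_T2 = rnorm(n), PSD_Cz_alpha_T1 = rnorm(n),
             BSR_F7_15mV_T3 = rnorm(n), age = rnorm(n))
  phi <- matrix(rnorm(4 * n), n, dimnames = list(NULL, colnames(X)))
  at <- structure(list(phi = phi, base = rep(0, n), X = X,
                       annotations = annotate_features(colnames(X))),
                  class = "attribution_table")
  cs <- category_summary(at)
  expect_equal(sum(cs$share), 1)
  cs2 <- category_summary(at, by = c("family", "band_class"))
  expect_equal(sum(cs2$share), 1)
  # all mass on one FC feature -> FC share 1
  phi1 <- phi * 0; phi1[, 1] <- 1
  at1 <- at; at1$phi <- phi1
  cs1 <- category_summary(at1)
  expect_equal(cs1$share[cs1$family == "FC"], 1)
  # symmetric two-feature attribution -> 0.5 / 0.5
  phi2 <- phi * 0; phi2[, 1] <- 1; phi2[, 2] <- -1
  at2 <- at; at2$phi <- phi2
  cs2 <- category_summary(at2)
  expect_equal(unname(cs2$share[cs2$family %in% c("FC", "PSD")]), c(0.5, 0.5))
  # sample order invariance
  atp <- at; ix <- sample(n); atp$phi <- at$phi[ix, ]; atp$X <- at$X[ix, ]
  expect_equal(category_summary(atp)$share, cs$share)
})

test_that("tendency flips sign when the feature is negated", {
  set.seed(75)
  n <- 60
  x <- rnorm(n)
  phi <- cbind(FC_Cz_Pz_alpha_T2 = x * 0.5, PSD_Cz_alpha_T1 = -x * 0.5)
  X <- cbind(FC_Cz_Pz_alpha_T2 = x, PSD_Cz_alpha_T1 = -x)
  at <- structure(list(phi = phi, base = rep(0, n), X = X,
                       annotations = annotate_features(colnames(X))),
                  class = "attribution_table")
  tt <- direction_tendency(at)
  expect_equal(tt$tendency, c("positive", "positive"))
  Xn <- X; Xn[, 1] <- -Xn[, 1]
  atn <- at; atn$X <- Xn
  expect_equal(direction_tendency(atn)$tendency[1], "negative")
})

test_that("top attributions rank by mean absolute value", {
  n <- 25
  X <- matrix(rnorm(3 * n), n,
              dimnames = list(NULL, c("FC_Cz_Pz_alpha_T2", "age", "PSD_Cz_alpha_T1")))
  phi <- cbind(rep(0.1, n), rep(2, n), rep(0.5, n))
  colnames(phi) <- colnames(X)
  at <- structure(list(phi = phi, base = rep(0, n), X = X,
                       annotations = annotate_features(colnames(X))),
                  class = "attribution_table")
  top <- top_attributions(at, k = 2)
  expect_equal(top$feature, c("age", "PSD_Cz_alpha_T1"))
})
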