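# small separable 2-D toy problem
toy_clusters <- function(n_per = 20L, sd = 0.3, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 0, sd), ncol = 2),
             matrix(rnorm(n_per * 2, 3, sd), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(0L, 1L), each = n_per))
}

test_that("metric suite matches independent hand computation on random confusion matrices", {
  set.seed(23)
  for (rep in 1:1000) {
    cnt <- sample(0:500, 4L, replace = TRUE)
    tp <- cnt[1]; tn <- cnt[2]; fp <- cnt[3]; fn <- cnt[4]
    m <- metrics_from_counts(tp, tn, fp, fn)
    sn <- if (tp + fn == 0) 0 else tp / (tp + fn)
    sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    tot <- tp + tn + fp + fn
    expect_equal(unname(m["acc"]), if (tot == 0) 0 else (tp + tn) / tot, tolerance = 1e-6)
    expect_equal(unname(m["sn"]), sn, tolerance = 1e-6)
    expect_equal(unname(m["sp"]), sp, tolerance = 1e-6)
    expect_equal(unname(m["precision"]), p, tolerance = 1e-6)
    expect_equal(unname(m["f1"]),
                 if (sn + p == 0) 0 else 2 * sn * p / (sn + p), tolerance = 1e-6)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(unname(m["mcc"]),
                 if (den == 0) 0 else (tp * tn - fp * fn) / den, tolerance = 1e-6)
    # mcc invariant under swapping (TP<->TN, FP<->FN)
    expect_equal(unname(m["mcc"]),
                 unname(metrics_from_counts(tn, tp, fn, fp)["mcc"]), tolerance = 1e-12)
  }
})

test_that("degenerate classifiers yield zero metrics, perfect ones yield one", {
  perfect <- metrics_from_counts(25, 25, 0, 0)
  expect_equal(unname(perfect[c("acc", "sn", "sp", "precision", "f1", "mcc")]),
               rep(1, 6))
  expect_equal(unname(metrics_from_counts(25, 25, 25, 25)["mcc"]), 0)
  all_neg <- metrics_from_counts(0, 50, 0, 50)
  expect_equal(unname(all_neg[c("sn", "precision", "f1", "mcc")]), rep(0, 4))
})

test_that("trapezoidal AUC reduces to (SN+SP)/2 for binary scores and matches pROC on graded ones", {
  set.seed(12)
  for (rep in 1:50) {
    labels <- sample(c(0L, 1L), 40, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    pred <- sample(c(0L, 1L), 40, replace = TRUE)
    a <- auc_trapezoid(pred, labels)
    sn <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    sp <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    expect_equal(a, (sn + sp) / 2, tolerance = 1e-12)

    scores <- runif(40)
    expect_equal(auc_trapezoid(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
})

test_that("auprc equals the step-sum average precision computed by hand", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  labels <- c(1, 0, 1, 1, 0)
  # thresholds descending: precision at each recall step
  want <- (1 / 3) * 1 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4)
  expect_equal(auprc(scores, labels), want, tolerance = 1e-12)
  expect_equal(auprc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
})

test_that("cross-validation is stratified, deterministic, and honest on separable data", {
  d <- toy_clusters(30L, seed = 2)
  cv <- cross_validate(model_spec("knn", neighbors = 3), d$x, d$y, folds = 10, seed = 3)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_length(cv$fold_accuracy, 10L)
  cv2 <- cross_validate(model_spec("knn", neighbors = 3), d$x, d$y, folds = 10, seed = 3)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$mean_accuracy, cv2$mean_accuracy)
  # folds are stratified: each fold holds 3 rows of each class
  for (f in 1:10)
    expect_equal(unname(table(d$y[cv$fold_assignment == f])), c(3L, 3L),
                 ignore_attr = TRUE)
  expect_error(cross_validate(model_spec("knn"), d$x[c(1:6, 31:36), ],
                              d$y[c(1:6, 31:36)], folds = 10),
               "at least 10")
})

test_that("each classifier family fits, predicts in [0,1], and memorizes separable data", {
  d <- toy_clusters(25L, seed = 4)
  for (spec in list(model_spec("svm", cost = 10, gamma = 0.5),
                    model_spec("rf", n_estimators = 100),
                    model_spec("logr", C = 70),
                    model_spec("knn", neighbors = 3, metric = "manhattan"))) {
    m <- fit_model(spec, d$x, d$y, seed = 5)
    pr <- predict_model(m, d$x)
    expect_true(all(pr >= 0 & pr <= 1), info = spec$algo)
    expect_gt(mean(as.integer(pr >= 0.5) == d$y), 0.95)
    # batch prediction preserves order and identical rows give identical outputs
    pr2 <- predict_model(m, d$x[c(1, 1, 2), ])
    expect_equal(pr2[1], pr2[2], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("knn distance metrics follow their formulas", {
  x <- rbind(c(0, 0), c(3, 4))
  y <- c(0L, 1L)
  m_eu <- fit_model(model_spec("knn", neighbors = 1, metric = "euclidean"), x, y)
  m_ma <- fit_model(model_spec("knn", neighbors = 1, metric = "manhattan"), x, y)
  m_mi <- fit_model(model_spec("knn", neighbors = 1, metric = "minkowski", p = 3), x, y)
  # query at (3,0): euclidean picks (0,0) [3 < 4]; manhattan ties go to first;
  # minkowski-3: d(origin)=3, d((3,4))=4 -> class 0
  q <- matrix(c(3, 0), 1)
  expect_equal(unname(predict_model(m_eu, q)), 0)
  expect_equal(unname(predict_model(m_mi, q)), 0)
  # query at (1,3): manhattan d=4 vs 3 -> class 1; euclidean sqrt(10) vs sqrt(5) -> class 1
  q2 <- matrix(c(1, 3), 1)
  expect_equal(unname(predict_model(m_ma, q2)), 1)
})

test_that("tuning returns a degenerate space unchanged and finds the exhaustive optimum", {
  d <- toy_clusters(15L, seed = 6)
  res <- tune(model_spec("knn"), list(neighbors = c(3, 3)), d$x, d$y,
              n_random = 1, folds = 3, seed = 1)
  expect_equal(res$best_params$neighbors, 3)
  expect_true(all(res$trace$neighbors == 3))

  # minority cluster drowned out at large k: accuracy decreases with k
  set.seed(9)
  x <- rbind(matrix(rnorm(40, 0, 1.2), ncol = 2),
             matrix(rnorm(8, 6, 0.2), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- c(rep(0L, 20), rep(1L, 4))
  space <- list(neighbors = c(1, 20))
  res <- tune(model_spec("knn"), space, x, y, n_random = 5, folds = 4, seed = 2)
  exhaustive <- vapply(1:20, function(k)
    cross_validate(model_spec("knn", neighbors = k), x, y, folds = 4,
                   seed = 2)$mean_accuracy, 0)
  expect_equal(res$cv_score, max(exhaustive), tolerance = 1e-12)
  # trace bookkeeping: stage-1 draws plus every coordinate-sweep evaluation
  expect_equal(sum(res$trace$stage == "random"), 5L)
  expect_equal(nrow(res$trace), 5L + sum(res$trace$stage == "grid"))
})

test_that("evaluate reproduces count metrics plus score-based areas", {
  d <- toy_clusters(25L, seed = 8)
  m <- fit_model(model_spec("rf", n_estimators = 100), d$x, d$y, seed = 1)
  rep <- evaluate(m, d$x, d$y)
  expect_s3_class(rep, "eval_report")
  expect_equal(unname(rep["acc"]), 1)
  expect_equal(unname(rep["auc"]), 1)
  expect_equal(unname(rep["auprc"]), 1)
})

test_that("published parameter sets carry the tuned values for all twelve combinations", {
  cfg <- published_params()
  expect_length(cfg, 12L)
  expect_equal(cfg$svm_smote$params[c("cost", "kernel", "gamma")],
               list(cost = 10, kernel = "rbf", gamma = 0.01))
  expect_equal(cfg$knn_nm$params[c("metric", "neighbors")],
               list(metric = "euclidean", neighbors = 7))
  expect_equal(cfg$logr_smote$params$C, 70)
  expect_equal(cfg$rf_smote$params[c("n_estimators", "max_depth", "bootstrap",
                                     "min_samples_leaf", "min_samples_split")],
               list(n_estimators = 1600, max_depth = 30, bootstrap = FALSE,
                    min_samples_leaf = 1, min_samples_split = 2))
  expect_equal(attr(cfg$svm_smote, "cv_score"), 0.99459)
})

test_that("trained models refuse inputs that do not match their feature layout", {
  d <- toy_clusters(10L, seed = 3)
  m <- fit_model(model_spec("logr"), d$x, d$y)
  expect_error(predict_model(m, d$x[, 1, drop = FALSE]), "mismatch")
  fx <- generate_fixtures(2, 2, seed = 1)
  expect_error(predict_hairpins(m, fx$records, fx$structures), "manifest")
})

test_that("high-level prediction memorizes training positives and preserves order", {
  fx <- generate_fixtures(15, 15, seed = 44)
  ds <- build_dataset(fx$records, fx$structures, fx$labels)
  xm <- as.matrix(ds[, feature_manifest()$name])
  sc <- fit_scaler(xm)
  m <- fit_model(model_spec("rf", n_estimators = 200), xm, ds$label,
                 scaler = sc, seed = 2)
  pred <- predict_hairpins(m, fx$records, fx$structures)
  expect_identical(pred$id, ds$id)
  expect_true(all(pred$probability[ds$label == 1L] > 0.5))
  pred2 <- predict_hairpins(m, fx$records, fx$structures)
  expect_identical(pred$probability, pred2$probability)
})
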