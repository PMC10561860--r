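#' Specify a classifier
#'
#' A lightweight specification of one of the four supported classifier
#' families and its hyperparameters, consumed by [fit_model()],
#' [cross_validate()] and [tune()].
#'
#' Supported parameters:
#' * `svm`: `cost`, `kernel` (`"linear"`, `"polynomial"`, `"rbf"`), `gamma`,
#'   `degree` (polynomial only).
#' * `rf`: `n_estimators`, `max_depth`, `bootstrap`, `min_samples_leaf`,
#'   `min_samples_split`.
#' * `logr`: `C` (inverse regularization strength); fitted by
#'   penalized (ridge) maximum likelihood.
#' * `knn`: `neighbors`, `metric` (`"euclidean"`, `"manhattan"`,
#'   `"minkowski"`), `p` (Minkowski order, default 3).
#'
#' @param algo One of `"svm"`, `"rf"`, `"logr"`, `"knn"`.
#' @param ... Hyperparameters (see above); unspecified ones take the
#'   family defaults.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algo = c("svm", "rf", "logr", "knn"), ...) {
  algo <- match.arg(algo)
  defaults <- switch(algo,
    svm = list(cost = 1, kernel = "rbf", gamma = 0.01, degree = 3),
    rf = list(n_estimators = 500, max_depth = 30, bootstrap = FALSE,
              min_samples_leaf = 1, min_samples_split = 2),
    logr = list(C = 70),
    knn = list(neighbors = 5, metric = "euclidean", p = 3))
  params <- utils::modifyList(defaults, list(...))
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop(sprintf("unknown %s parameter(s): %s", algo, paste(bad, collapse = ", ")))
  structure(list(algo = algo, params = params), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %s\n", x$algo,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Fit a classifier
#'
#' Trains the classifier described by a [model_spec()] on a feature matrix
#' and binary labels. If a [fit_scaler()] object is supplied it is stored
#' with the model and applied automatically at prediction time. The model
#' records the feature-manifest version and refuses to predict on vectors
#' that do not match it.
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix (rows = examples).
#' @param y Binary labels (0/1).
#' @param scaler Optional fitted `feature_scaler` (applied to `x` here and
#'   to new data at prediction time).
#' @param seed Integer seed controlling every stochastic element of the
#'   fit (e.g. forest bootstrap).
#' @return An object of class `trained_model` with fields `algo`,
#'   `params`, `fit`, `scaler`, `manifest_version`, `seed` and
#'   (optionally, from [cross_validate()]) `cv_score`.
#' @export
fit_model <- function(spec, x, y, scaler = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (!is.null(scaler)) x <- apply_scaler(scaler, x)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  p <- spec$params
  fit <- switch(spec$algo,
    svm = {
      kernel <- switch(p$kernel, rbf = "radial", p$kernel)
      e1071::svm(x, factor(y, levels = c(0L, 1L)), type = "C-classification",
                 kernel = kernel, cost = p$cost, gamma = p$gamma,
                 degree = p$degree, probability = TRUE, scale = FALSE)
    },
    rf = {
      df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = p$n_estimators,
                     max.depth = p$max_depth,
                     min.node.size = p$min_samples_split,
                     min.bucket = p$min_samples_leaf,
                     replace = p$bootstrap,
                     sample.fraction = 1,
                     probability = TRUE, seed = seed, num.threads = 1L)
    },
    logr = {
      # ridge-penalized logistic regression; C is the inverse penalty on
      # the summed loss, so lambda = 1 / (C * n) on glmnet's mean-loss scale
      glmnet::glmnet(x, factor(y, levels = c(0L, 1L)), family = "binomial",
                     alpha = 0, lambda = 1 / (p$C * nrow(x)))
    },
    knn = list(x = x, y = y, k = p$neighbors, metric = p$metric, p = p$p))
  structure(list(algo = spec$algo, params = p, fit = fit, scaler = scaler,
                 manifest_version = if (ncol(x) == 93L) manifest_version() else NA_character_,
                 n_features = ncol(x), seed = seed, cv_score = NA_real_),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s (%d features%s)\n", x$algo, x$n_features,
              if (!is.na(x$cv_score)) sprintf(", CV accuracy %.4f", x$cv_score) else ""))
  invisible(x)
}

#' Predict positive-class probabilities
#'
#' @param model A [fit_model()] result.
#' @param x Feature matrix of new examples (unscaled; the stored scaler,
#'   if any, is applied).
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict_model <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 model$n_features, ncol(x)))
  if (!is.null(model$scaler)) x <- apply_scaler(model$scaler, x)
  switch(model$algo,
    svm = {
      pr <- predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = {
      colnames(x) <- model$fit$forest$independent.variable.names
      predict(model$fit, data.frame(x, check.names = FALSE),
              num.threads = 1L)$predictions[, "1"]
    },
    logr = as.vector(predict(model$fit, x, type = "response")),
    knn = knn_prob(model$fit, x))
}

knn_prob <- function(fit, x) {
  pow <- switch(fit$metric, euclidean = 2, manhattan = 1, minkowski = fit$p,
                stop("unknown KNN metric"))
  k_eff <- min(fit$k, nrow(fit$x))
  apply(x, 1L, function(q) {
    d <- rowSums(abs(sweep(fit$x, 2L, q))^pow)^(1 / pow)
    nn <- order(d)[seq_len(k_eff)]
    mean(fit$y[nn] == 1L)
  })
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `folds` stratified parts, trains on all but one
#' and scores accuracy on the held-out part, and returns the mean across
#' folds (the CV score used for hyperparameter selection).
#'
#' @param spec A [model_spec()].
#' @param x Feature matrix.
#' @param y Binary labels (0/1); each class needs at least `folds` rows.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @return A list: `mean_accuracy`, `fold_accuracy` (per-fold vector),
#'   `fold_assignment`.
#' @export
cross_validate <- function(spec, x, y, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || any(table(y) < folds))
    stop(sprintf("each class needs at least %d rows for %d-fold CV", folds, folds))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  assignment <- integer(length(y))
  for (lab in unique(y)) {
    idx <- sample(which(y == lab))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- assignment != f
    model <- fit_model(spec, x[tr, , drop = FALSE], y[tr], seed = seed)
    prob <- predict_model(model, x[!tr, , drop = FALSE])
    mean(as.integer(prob >= 0.5) == y[!tr])
  }, 0)
  list(mean_accuracy = mean(acc), fold_accuracy = acc, fold_assignment = assignment)
}

#' Randomized-then-coordinate hyperparameter tuning
#'
#' Two-stage search over a hyperparameter space, scored by stratified
#' k-fold CV accuracy. Stage 1 draws `n_random` configurations uniformly
#' from the space. Stage 2 refines the best configuration coordinate-wise:
#' one parameter at a time is swept over a local grid while the others are
#' held fixed, repeating until no parameter changes. Ties are broken
#' toward the simpler model (smaller numeric value: fewer trees, smaller
#' cost, fewer neighbours).
#'
#' @param spec A [model_spec()] naming the algorithm (its parameter values
#'   are the search's starting point).
#' @param space Named list of parameter ranges: numeric `c(lo, hi)` for
#'   continuous/integer parameters, or a character/logical vector of
#'   admissible values for discrete ones.
#' @param x,y Training matrix and binary labels.
#' @param n_random Number of stage-1 random draws.
#' @param folds CV folds per evaluation.
#' @param grid_points Local-grid size per coordinate sweep.
#' @param max_sweeps Safety cap on stage-2 rounds.
#' @param seed Integer seed.
#' @return A list: `best_params`, `cv_score`, and `trace` (a data frame
#'   with one row per evaluated configuration).
#' @export
tune <- function(spec, space, x, y, n_random = 10L, folds = 5L,
                 grid_points = 5L, max_sweeps = 5L, seed = 1L) {
  if (!length(space)) stop("empty hyperparameter space")
  is_int <- vapply(space, function(r) is.numeric(r) && all(r == round(r)), TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  draw <- function() {
    cfg <- lapply(names(space), function(nm) {
      r <- space[[nm]]
      if (is.numeric(r)) {
        v <- runif(1, min(r), max(r))
        if (is_int[[nm]]) round(v) else v
      } else sample(r, 1L)
    })
    setNames(cfg, names(space))
  }
  score_of <- function(cfg) {
    s <- do.call(model_spec, c(list(algo = spec$algo),
                               utils::modifyList(spec$params, cfg)))
    cross_validate(s, x, y, folds = folds, seed = seed)$mean_accuracy
  }
  complexity <- function(cfg) sum(vapply(cfg, function(v)
    if (is.numeric(v)) v else 0, 0))

  trace <- list()
  note <- function(cfg, sc, stage) {
    trace[[length(trace) + 1L]] <<- data.frame(stage = stage, score = sc,
      lapply(cfg, function(v) if (is.logical(v)) as.logical(v) else v),
      stringsAsFactors = FALSE)
  }

  best_cfg <- NULL; best_score <- -Inf
  consider <- function(cfg, sc) {
    better <- sc > best_score + 1e-12 ||
      (abs(sc - best_score) <= 1e-12 && !is.null(best_cfg) &&
         complexity(cfg) < complexity(best_cfg))
    if (is.null(best_cfg) || better) { best_cfg <<- cfg; best_score <<- sc }
  }
  for (i in seq_len(max(1L, n_random))) {
    cfg <- draw()
    sc <- score_of(cfg)
    note(cfg, sc, "random")
    consider(cfg, sc)
  }
  # coordinate-wise grid refinement: fix best-so-far, sweep one parameter
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- FALSE
    for (nm in names(space)) {
      r <- space[[nm]]
      candidates <- if (is.numeric(r)) {
        cur <- best_cfg[[nm]]
        width <- (max(r) - min(r)) / 2^sweep_i
        g <- seq(max(min(r), cur - width), min(max(r), cur + width),
                 length.out = grid_points)
        if (is_int[[nm]]) unique(round(g)) else unique(g)
      } else r
      for (v in candidates) {
        if (identical(v, best_cfg[[nm]])) next
        cfg <- best_cfg
        cfg[[nm]] <- v
        sc <- score_of(cfg)
        note(cfg, sc, "grid")
        if (sc > best_score + 1e-12 ||
            (abs(sc - best_score) <= 1e-12 && complexity(cfg) < complexity(best_cfg))) {
          best_cfg <- cfg; best_score <- sc; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(best_params = best_cfg, cv_score = best_score,
       trace = do.call(rbind, trace))
}

#' Evaluate a trained model on a test set
#'
#' Predicts probabilities on `x` and scores them against `y` with the full
#' metric suite ([evaluate_scores()]).
#'
#' @param model A [fit_model()] result.
#' @param x Test feature matrix.
#' @param y Binary test labels (0/1).
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_report`.
#' @export
evaluate <- function(model, x, y, threshold = 0.5) {
  evaluate_scores(predict_model(model, x), y, threshold = threshold)
}

#' Best published hyperparameter sets
#'
#' The tuned best-parameter configurations for each of the twelve
#' (algorithm x balancing-strategy) combinations -- SMOTE-balanced,
#' Near-Miss-balanced and unbalanced training -- as ready-to-fit
#' [model_spec()]s, each carrying the reported 10-fold CV accuracy in
#' attribute `cv_score`.
#'
#' @return Named list of twelve `model_spec`s: `svm_smote`, `svm_nm`,
#'   `svm_imbalance`, `rf_smote`, ..., `knn_imbalance`.
#' @export
published_params <- function() {
  with_cv <- function(spec, cv) { attr(spec, "cv_score") <- cv; spec }
  list(
    svm_smote = with_cv(model_spec("svm", cost = 10, kernel = "rbf", gamma = 0.01), 0.99459),
    svm_nm = with_cv(model_spec("svm", cost = 1, kernel = "rbf", gamma = 0.001), 0.952789),
    svm_imbalance = with_cv(model_spec("svm", cost = 6, kernel = "rbf", gamma = 0.001), 0.96871),
    rf_smote = with_cv(model_spec("rf", n_estimators = 1600, max_depth = 30,
                                  bootstrap = FALSE, min_samples_leaf = 1,
                                  min_samples_split = 2), 0.98609),
    rf_nm = with_cv(model_spec("rf", n_estimators = 1400, max_depth = 30,
                               bootstrap = FALSE, min_samples_leaf = 1,
                               min_samples_split = 2), 0.944617),
    rf_imbalance = with_cv(model_spec("rf", n_estimators = 30, max_depth = 10,
                                      bootstrap = FALSE, min_samples_leaf = 2,
                                      min_samples_split = 2), 0.96281),
    logr_smote = with_cv(model_spec("logr", C = 70), 0.9627),
    logr_nm = with_cv(model_spec("logr", C = 100), 0.946952),
    logr_imbalance = with_cv(model_spec("logr", C = 30), 0.96703),
    knn_smote = with_cv(model_spec("knn", neighbors = 2, metric = "manhattan"), 0.98199),
    knn_nm = with_cv(model_spec("knn", neighbors = 7, metric = "euclidean"), 0.92166),
    knn_imbalance = with_cv(model_spec("knn", neighbors = 7, metric = "euclidean"), 0.96032))
}

#' Predict hairpin class for new records
#'
#' High-level prediction: featurizes each (record, structure) pair,
#' applies the model's stored scaler, and returns label and probability
#' per record (label 1 iff probability >= 0.5).
#'
#' @param model A [fit_model()] result trained on the 93-feature manifest.
#' @param records List of [rna_record]s.
#' @param structures List of matching [secondary_structure]s with
#'   `pair_probs`.
#' @inheritParams featurize_set
#' @return Data frame: `id`, `label`, `probability`, in input order.
#' @export
predict_hairpins <- function(model, records, structures, backend = NULL,
                             n_shuffles = 0L, seed = 1L) {
  if (is.na(model$manifest_version) ||
      !identical(model$manifest_version, manifest_version()))
    stop("model was not trained on the current 93-feature manifest")
  m <- featurize_set(records, structures, backend = backend,
                     n_shuffles = n_shuffles, seed = seed)
  prob <- predict_model(model, m)
  data.frame(id = rownames(m), label = as.integer(prob >= 0.5),
             probability = as.numeric(prob),
             row.names = NULL, stringsAsFactors = FALSE)
}
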