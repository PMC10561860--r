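#' SMOTE minority oversampling
#'
#' Raises the minority class to the majority count by synthesizing points
#' on segments between minority neighbours: for each synthetic sample a
#' minority point `x` is drawn, one of its `k` nearest minority
#' neighbours `x'` (Euclidean distance) is drawn, and `x + u * (x' - x)`
#' with `u ~ Uniform(0, 1)` is emitted. Apply to training rows only, after
#' scaling, so synthetic points never leak into evaluation.
#'
#' @param x Numeric feature matrix (training rows).
#' @param labels Binary labels (0/1) aligned to `x`.
#' @param k Number of minority nearest neighbours (default 5).
#' @param seed Integer seed; output is bit-reproducible.
#' @return A list of class `balanced_dataset`: `x`, `labels`, `synthetic`
#'   (logical flag per row), `method`, `k`, `seed`, `counts_before`,
#'   `counts_after`.
#' @export
smote <- function(x, labels, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0L, 1L)))
  counts <- table(factor(labels, levels = c(0L, 1L)))
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < k + 1L)
    stop(sprintf("minority class has %d members but k = %d needs at least %d; use a smaller k",
                 n_min, k, k + 1L))
  min_idx <- which(labels == minority)
  xm <- x[min_idx, , drop = FALSE]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  n_new <- n_maj - n_min
  synth <- matrix(0, n_new, ncol(x))
  if (n_new > 0L) {
    d <- as.matrix(dist(xm))
    diag(d) <- Inf
    nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
    base_pick <- sample.int(n_min, n_new, replace = TRUE)
    nb_pick <- sample.int(k, n_new, replace = TRUE)
    u <- runif(n_new)
    for (s in seq_len(n_new)) {
      a <- xm[base_pick[s], ]
      b <- xm[nn[base_pick[s], nb_pick[s]], ]
      synth[s, ] <- a + u[s] * (b - a)
    }
  }
  colnames(synth) <- colnames(x)
  out_x <- rbind(x, synth)
  out_labels <- c(labels, rep(minority, n_new))
  structure(list(x = out_x, labels = out_labels,
                 synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)),
                 method = "smote", k = k, seed = seed,
                 counts_before = as.vector(counts),
                 counts_after = as.vector(table(factor(out_labels, levels = c(0L, 1L))))),
            class = "balanced_dataset")
}

#' Near-Miss (version 1) majority undersampling
#'
#' Shrinks the majority class to the minority count by keeping the
#' majority points with the smallest mean Euclidean distance to their `k`
#' nearest minority points. No synthetic rows are created. Versions 2
#' (farthest minority points) and 3 are selectable for comparison.
#'
#' @param x Numeric feature matrix (training rows).
#' @param labels Binary labels (0/1) aligned to `x`.
#' @param k Number of minority neighbours in the mean distance (default 3).
#' @param version Near-Miss variant: 1 (default) or 2.
#' @param seed Integer seed (used only to break exact distance ties).
#' @return A `balanced_dataset` (see [smote()]); `synthetic` is all FALSE.
#' @export
nearmiss <- function(x, labels, k = 3L, version = 1L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0L, 1L)))
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (counts[1] == counts[2]) {
    warning("classes already balanced; returning the input unchanged")
    return(structure(list(x = x, labels = labels,
                          synthetic = rep(FALSE, nrow(x)), kept = seq_len(nrow(x)),
                          method = "nearmiss", k = k, seed = seed,
                          counts_before = as.vector(counts),
                          counts_after = as.vector(counts)),
                     class = "balanced_dataset"))
  }
  minority <- as.integer(names(which.min(counts)))
  maj_idx <- which(labels != minority)
  min_idx <- which(labels == minority)
  k_eff <- min(k, length(min_idx))
  # mean distance from each majority point to its k nearest (version 1)
  # or k farthest (version 2) minority points
  score <- vapply(maj_idx, function(i) {
    d <- sqrt(colSums((t(x[min_idx, , drop = FALSE]) - x[i, ])^2))
    d <- sort(d, decreasing = (version == 2L))
    mean(d[seq_len(k_eff)])
  }, 0)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  keep_maj <- maj_idx[order(score, runif(length(score)))][seq_len(min(counts))]
  keep <- sort(c(min_idx, keep_maj))
  structure(list(x = x[keep, , drop = FALSE], labels = labels[keep],
                 synthetic = rep(FALSE, length(keep)), kept = keep,
                 method = "nearmiss", k = k, seed = seed,
                 counts_before = as.vector(counts),
                 counts_after = as.vector(table(factor(labels[keep], levels = c(0L, 1L))))),
            class = "balanced_dataset")
}

#' Balance the training partition of a dataset table
#'
#' Convenience wrapper: takes a dataset with a `split` column, balances
#' only the training rows with [smote()] or [nearmiss()], and returns a
#' table with a `synthetic` column. Test rows are passed through
#' untouched.
#'
#' @param dataset Data frame from [build_dataset()] + [split_dataset()].
#' @param method `"smote"`, `"nearmiss"` or `"none"`.
#' @param ... Passed to the balancing function.
#' @return A data frame in the same layout with training rows rebalanced.
#' @export
balance_training <- function(dataset, method = c("smote", "nearmiss", "none"), ...) {
  method <- match.arg(method)
  if (is.null(dataset$split)) stop("dataset has no 'split' column; run split_dataset() first")
  train <- dataset[dataset$split == "train", , drop = FALSE]
  test <- dataset[dataset$split != "train", , drop = FALSE]
  test$synthetic <- FALSE
  if (method == "none") {
    train$synthetic <- FALSE
    return(rbind(train, test))
  }
  bal <- switch(method,
                smote = smote(dataset_matrix(train), train$label, ...),
                nearmiss = nearmiss(dataset_matrix(train), train$label, ...))
  orig_rows <- if (bal$method == "nearmiss") train[bal$kept, , drop = FALSE] else train
  out <- data.frame(id = c(orig_rows$id,
                           sprintf("synthetic_%04d", seq_len(sum(bal$synthetic)))),
                    as.data.frame(bal$x, check.names = FALSE),
                    label = bal$labels, split = "train",
                    synthetic = bal$synthetic,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, test[, colnames(out), drop = FALSE])
}
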