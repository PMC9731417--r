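#' Built-in classifiers
#'
#' Returns a training/prediction closure `f(train_x, train_y, test_x)` for
#' one of the supported classifiers: `"rf"` (random forest, 100 trees),
#' `"knn"` (k = 5 nearest neighbours on z-scored features, scaling fitted on
#' the training fold only) or `"dt"` (CART decision tree, Gini impurity, no
#' complexity pruning). A function passed in is returned unchanged, which
#' allows test stubs.
#'
#' @param classifier Name or function.
#' @param n_trees Random forest ensemble size.
#' @param knn_k Neighbour count for `"knn"`.
#' @return A function `(train_x, train_y, test_x) -> factor predictions`.
#' @export
make_classifier <- function(classifier, n_trees = 100L, knn_k = 5L) {
  if (is.function(classifier)) return(classifier)
  switch(match.arg(classifier, c("rf", "knn", "dt")),
    rf = function(train_x, train_y, test_x) {
      fit <- randomForest::randomForest(x = train_x, y = train_y,
                                        ntree = n_trees)
      stats::predict(fit, test_x)
    },
    knn = function(train_x, train_y, test_x) {
      mu <- colMeans(train_x)
      sd_ <- apply(train_x, 2, stats::sd)
      sd_[sd_ == 0] <- 1
      tr <- scale(train_x, mu, sd_)
      te <- scale(test_x, mu, sd_)
      class::knn(tr, te, train_y, k = knn_k)
    },
    dt = function(train_x, train_y, test_x) {
      df <- data.frame(train_x, .y = train_y, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          control = rpart::rpart.control(cp = 0, xval = 0))
      stats::predict(fit, data.frame(test_x, check.names = FALSE),
                     type = "class")
    })
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin, so fold class proportions differ by at most one member.
stratified_folds <- function(labels, folds, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", folds, ")")
    }
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cohen's kappa from a confusion matrix
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement `p_o` the
#' diagonal fraction and expected agreement
#' \eqn{p_e = \sum_k row_k \cdot col_k / n^2}. Defined as 0 (with a
#' warning) when `p_e = 1`.
#'
#' @param confusion Square count matrix (true in rows, predicted in columns).
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  stopifnot(n > 0, nrow(confusion) == ncol(confusion))
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Stratified k-fold cross-validation
#'
#' Splits the samples into stratified folds, trains the classifier on each
#' training fold, pools the out-of-fold predictions over all n samples, and
#' computes accuracy, Cohen's kappa, and the confusion matrix on the pooled
#' predictions (so correct + error counts sum to n). Deterministic given
#' `seed`.
#'
#' @param M A [feature_matrix()].
#' @param classifier Name (`"rf"`, `"knn"`, `"dt"`) or function; see
#'   [make_classifier()].
#' @param folds Number of folds; every class must have at least this many
#'   members.
#' @param seed Integer seed governing fold assignment and classifier
#'   randomness.
#' @return List with `accuracy`, `kappa`, `confusion`, `correct`, `error`,
#'   `predictions`, `fold`.
#' @export
stratified_kfold_cv <- function(M, classifier = "rf", folds = 10L, seed = 1L) {
  fn <- make_classifier(classifier)
  fold <- stratified_folds(M$labels, folds, seed)
  preds <- factor(rep(NA_character_, length(M$labels)), levels = levels(M$labels))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed + 1L)
  for (f in seq_len(folds)) {
    te <- fold == f
    p <- fn(M$values[!te, , drop = FALSE], M$labels[!te],
            M$values[te, , drop = FALSE])
    preds[te] <- factor(as.character(p), levels = levels(M$labels))
  }
  confusion <- table(true = M$labels, predicted = preds)
  correct <- sum(diag(confusion))
  list(accuracy = correct / length(M$labels),
       kappa = cohen_kappa(confusion),
       confusion = confusion,
       correct = correct,
       error = length(M$labels) - correct,
       predictions = preds,
       fold = fold)
}

#' Classification accuracy as a percentage
#'
#' @param correct Number of correctly classified samples.
#' @param total Total sample count (> 0).
#' @return `100 * correct / total`.
#' @export
accuracy_from_counts <- function(correct, total) {
  stopifnot(total > 0, correct >= 0, correct <= total)
  100 * correct / total
}

#' Incremental top-k feature classification curve
#'
#' For k = 1..p, runs [stratified_kfold_cv()] on the k best-ranked features
#' and records the accuracy curve. The reported operating point is the
#' smallest k attaining the maximal accuracy; kappa, confusion and
#' correct/error counts are recomputed there.
#'
#' @param M A [feature_matrix()].
#' @param ranking A `ranking_result` for the same features.
#' @param classifier Name or function; see [make_classifier()].
#' @param folds CV folds.
#' @param seed Integer seed (fold assignment is shared across k).
#' @param ks Subset of feature counts to evaluate (default `1:p`).
#' @return An object of class `cv_result`.
#' @export
incremental_curve <- function(M, ranking, classifier = "rf", folds = 10L,
                              seed = 1L, ks = seq_len(ncol(M$values))) {
  stopifnot(identical(ranking$feature_names, M$feature_names))
  top_k <- function(k) {
    sub <- M
    # keep the original column order so k = p is byte-identical to the full
    # matrix (tree fitting is not invariant to column permutation)
    keep <- sort(ranking$order[seq_len(k)])
    sub$values <- M$values[, keep, drop = FALSE]
    sub$feature_names <- M$feature_names[keep]
    sub
  }
  acc <- vapply(ks, function(k) {
    stratified_kfold_cv(top_k(k), classifier, folds, seed)$accuracy
  }, numeric(1))
  best_k <- ks[order(-acc, ks)[1]]
  best <- stratified_kfold_cv(top_k(best_k), classifier, folds, seed)
  structure(list(curve = data.frame(k = ks, accuracy = acc),
                 best_k = best_k, best_accuracy = best$accuracy,
                 kappa = best$kappa, correct = best$correct,
                 error = best$error, confusion = best$confusion,
                 ranker = ranking$method,
                 classifier = if (is.character(classifier)) classifier else "custom",
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result %s/%s: best k=%d ACC=%.2f%% kappa=%.2f%% (%d correct & %d error)>\n",
    x$ranker, x$classifier, x$best_k, 100 * x$best_accuracy, 100 * x$kappa,
    x$correct, x$error))
  invisible(x)
}

#' Stratified holdout split
#'
#' Splits a feature matrix into disjoint, exhaustive train/test parts,
#' preserving class proportions (per class, `round(fraction * n_c)` members
#' go to training). Deterministic given `seed`.
#'
#' @param M A [feature_matrix()].
#' @param train_fraction Fraction in (0, 1) assigned to training.
#' @param seed Integer seed.
#' @return List with `train` and `test` feature matrices and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
holdout_split <- function(M, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  tr <- integer(0)
  for (cl in levels(M$labels)) {
    idx <- which(M$labels == cl)
    n_tr <- min(max(1L, round(train_fraction * length(idx))), length(idx) - 1L)
    tr <- c(tr, sample(idx, n_tr))
  }
  tr <- sort(tr)
  te <- setdiff(seq_along(M$labels), tr)
  subset_fm <- function(i) {
    out <- M
    out$values <- M$values[i, , drop = FALSE]
    out$labels <- M$labels[i]
    out
  }
  list(train = subset_fm(tr), test = subset_fm(te),
       train_idx = tr, test_idx = te)
}

#' Write the incremental accuracy curve to CSV
#'
#' Two columns, `k` and `accuracy`, one row per evaluated feature count —
#' the inputs of accuracy-versus-dimension plots.
#'
#' @param result A `cv_result`.
#' @param path Output path.
#' @export
write_curve_csv <- function(result, path) {
  utils::write.csv(result$curve, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a CV result to JSON
#' @param result A `cv_result`.
#' @param path Output path.
#' @export
write_cv_json <- function(result, path) {
  out <- unclass(result)
  out$confusion <- as.data.frame.matrix(result$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
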