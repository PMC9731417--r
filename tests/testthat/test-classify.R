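make_balanced <- function(n = 200, classes = 5, p = 4, seed = 1) {
  set.seed(seed)
  y <- factor(rep(letters[seq_len(classes)], each = n / classes))
  df <- data.frame(matrix(rnorm(n * p), n, p), label = y)
  feature_matrix(df)
}

test_that("pooled CV metrics are exact for perfect and constant stubs", {
  M <- make_balanced()
  truth <- M$labels
  # an oracle stub that recovers the held-out truth by matching rows
  fn <- function(tx, ty, sx) truth[match(apply(sx, 1, paste, collapse = ","),
                                         apply(M$values, 1, paste, collapse = ","))]
  cv <- stratified_kfold_cv(M, fn, folds = 10, seed = 2)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$kappa, 1)
  expect_identical(cv$correct + cv$error, length(M$labels))
  const <- function(tx, ty, sx) factor(rep(levels(ty)[1], nrow(sx)),
                                       levels = levels(ty))
  cv0 <- stratified_kfold_cv(M, const, folds = 10, seed = 2)
  expect_equal(cv0$accuracy, 0.2)
  expect_equal(cv0$kappa, 0)
})

test_that("fold assignment is stratified within one member per fold", {
  M <- make_balanced(n = 205, classes = 5)  # 41 per class over 10 folds
  fold <- pcgfusion:::stratified_folds(M$labels, 10, 3)
  tab <- table(fold, M$labels)
  expect_lte(max(tab) - min(tab), 1)
  expect_error(pcgfusion:::stratified_folds(factor(rep(c("a", "b"), c(5, 50))),
                                            10, 1),
               "'a'")
})

test_that("Cohen's kappa matches hand arithmetic and its invariances", {
  expect_equal(cohen_kappa(diag(c(10, 20, 30))), 1)
  expect_equal(cohen_kappa(matrix(c(40, 10, 10, 40), 2, 2)), 0.6)
  m <- matrix(c(35, 5, 10, 50), 2, 2)
  expect_equal(cohen_kappa(m), cohen_kappa(10 * m))
  expect_warning(k <- cohen_kappa(matrix(c(10, 0, 0, 0), 2, 2)), "agreement")
  expect_equal(k, 0)
})

test_that("accuracy percentages reproduce the reported count arithmetic", {
  expect_equal(accuracy_from_counts(993, 1000), 99.30)
  expect_equal(accuracy_from_counts(990, 1000), 99.00)
  expect_equal(accuracy_from_counts(0, 7), 0)
  expect_error(accuracy_from_counts(5, 0))
  expect_error(accuracy_from_counts(8, 7))
})

test_that("the incremental curve is consistent and finds small subsets", {
  set.seed(6)
  n <- 300
  y <- factor(rep(letters[1:5], each = n / 5))
  mu <- as.integer(y)
  df <- data.frame(a = mu + rnorm(n, 0, 0.2), b = (mu %% 2) + rnorm(n, 0, 0.2),
                   c = (mu %% 3) + rnorm(n, 0, 0.2), n1 = rnorm(n),
                   n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n), label = y)
  M <- feature_matrix(df)
  r <- tree_rank(M, seed = 2)
  cv <- incremental_curve(M, r, "rf", folds = 5, seed = 2)
  p <- ncol(M$values)
  expect_identical(nrow(cv$curve), p)
  full <- stratified_kfold_cv(M, "rf", folds = 5, seed = 2)
  expect_equal(cv$curve$accuracy[p], full$accuracy)
  expect_lte(cv$best_k, 5)
  acc3 <- cv$curve$accuracy[3]
  expect_gte(acc3, cv$curve$accuracy[p] - 0.02)
  expect_equal(cv$best_accuracy, max(cv$curve$accuracy))
  # smallest k wins ties
  expect_false(any(cv$curve$accuracy[seq_len(cv$best_k - 1)] >=
                     cv$best_accuracy))
})

test_that("all three classifiers train and predict through the CV harness", {
  set.seed(7)
  n <- 150
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  df <- data.frame(f = as.integer(y) + rnorm(n, 0, 0.2), g = rnorm(n),
                   label = y)
  M <- feature_matrix(df)
  for (clf in c("rf", "knn", "dt")) {
    cv <- stratified_kfold_cv(M, clf, folds = 5, seed = 1)
    expect_gt(cv$accuracy, 0.8)
    expect_equal(sum(cv$confusion), n)
  }
})

test_that("holdout splits are stratified, disjoint, and exhaustive", {
  df <- data.frame(f = rnorm(1000), label = rep(letters[1:5], each = 200))
  M <- feature_matrix(df)
  hs <- holdout_split(M, 0.8, seed = 3)
  expect_identical(length(hs$train_idx), 800L)
  expect_identical(length(hs$test_idx), 200L)
  expect_identical(sort(c(hs$train_idx, hs$test_idx)), 1:1000)
  expect_true(all(table(hs$train$labels) == 160))
  hs2 <- holdout_split(M, 0.8, seed = 3)
  expect_identical(hs$train_idx, hs2$train_idx)
})

test_that("CV results serialize to JSON", {
  M <- make_balanced(n = 100)
  r <- tree_rank(M, seed = 1)
  cv <- incremental_curve(M, r, "rf", folds = 5, seed = 1, ks = c(1, 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_json(cv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$best_accuracy, cv$best_accuracy)
  expect_identical(nrow(back$curve), 2L)
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, pcsv)
  curve <- read.csv(pcsv)
  expect_identical(names(curve), c("k", "accuracy"))
  expect_equal(curve$accuracy, cv$curve$accuracy)
})
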