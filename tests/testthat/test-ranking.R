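test_that("mutual information matches exact joint-histogram arithmetic", {
  y <- factor(rep(c("a", "b"), each = 50))
  x <- as.integer(y)                       # perfect dependence, balanced
  expect_equal(mutual_information(x, y), log(2), tolerance = 1e-9)
  set.seed(1)
  xp <- sample(x)                          # permuted: independent
  expect_lt(mutual_information(xp, y), 0.05)
  expect_equal(mutual_information(rep(1, 100), y), 0)
  # discretized input: equals the plug-in estimator computed by hand
  set.seed(2)
  xd <- sample(1:4, 200, replace = TRUE)
  yd <- factor(sample(c("u", "v", "w"), 200, replace = TRUE))
  tab <- table(xd, yd)
  pxy <- tab / sum(tab)
  mi_hand <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (pxy[i, j] > 0) {
      mi_hand <- mi_hand +
        pxy[i, j] * log(pxy[i, j] / (sum(pxy[i, ]) * sum(pxy[, j])))
    }
  }
  expect_equal(mutual_information(xd, yd), mi_hand, tolerance = 1e-12)
})

test_that("independent continuous features carry little mutual information", {
  set.seed(3)
  y <- factor(rep(letters[1:5], each = 200))
  mi <- mutual_information(rnorm(1000), y)
  expect_lt(mi, 0.05)
})

test_that("mRMR picks the most relevant feature first and punishes copies", {
  M <- feature_matrix(canonical_table())
  r <- mrmr_rank(M)
  rel <- apply(M$values, 2, mutual_information, y = M$labels)
  expect_identical(r$order[1], unname(which.max(rel)))
  expect_true(informative_above_noise(r))
  # 3-feature construction: f2 an exact copy of f1, f3 weakly informative
  set.seed(21)
  n <- 300
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  f1 <- as.integer(y) + rnorm(n, 0, 0.3)
  df <- data.frame(f1 = f1, f2 = f1, f3 = 0.4 * (as.integer(y) %% 2) +
                     rnorm(n, 0, 0.4), label = y)
  r3 <- mrmr_rank(feature_matrix(df))
  expect_identical(r3$order, c(1L, 3L, 2L))
  # greedy agreement with an independent oracle for the first picks
  red <- pcgfusion:::feature_mi_matrix(M)
  sel <- integer(0); remaining <- seq_len(ncol(M$values))
  for (step in 1:3) {
    crit <- sapply(remaining, function(f) {
      if (!length(sel)) rel[f] else rel[f] - mean(red[f, sel])
    })
    pick <- remaining[order(-crit, remaining)[1]]
    sel <- c(sel, pick); remaining <- setdiff(remaining, pick)
  }
  expect_identical(r$order[1:3], sel)
})

test_that("the KCCA gate keeps copy redundancy and drops noise-only links", {
  set.seed(21)
  n <- 300
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  mu <- as.integer(y)
  f1 <- mu + rnorm(n, 0, 0.3)
  f2 <- f1 + rnorm(n, 0, 0.01)
  z <- rnorm(n)
  g1 <- z + rnorm(n, 0, 0.3)
  g2 <- z + rnorm(n, 0, 0.3)
  rho_copy <- pcgfusion:::kcca_label_cor(f1, f2, y)
  rho_noise <- pcgfusion:::kcca_label_cor(g1, g2, y)
  expect_gt(rho_copy, 0.3)
  expect_lt(rho_noise, 0.3)
  # copy still punished, ranked last, as in plain mRMR
  f3 <- 0.3 * (mu %% 2) + rnorm(n, 0, 0.4)
  M <- feature_matrix(data.frame(f1 = f1, f2 = f2, f3 = f3, label = y))
  expect_identical(kcca_mrmr_rank(M)$order, c(1L, 3L, 2L))
  # noise-linked pair: redundancy penalty strictly smaller than plain mRMR
  Mn <- feature_matrix(data.frame(f1 = f1, g1 = g1, g2 = g2, label = y))
  red <- pcgfusion:::feature_mi_matrix(Mn)
  expect_gt(red[2, 3], 0.3)                 # mRMR would charge this
  expect_lt(rho_noise, 0.3)                 # the gate zeroes it
  # infinite regularization: relevance-only ordering
  rel <- apply(M$values, 2, mutual_information, y = M$labels)
  r_inf <- kcca_mrmr_rank(M, reg = 1e8)
  expect_identical(r_inf$order, order(-rel, seq_along(rel)))
})

test_that("QPFS weights solve the simplex-constrained program", {
  M <- feature_matrix(canonical_table())
  r <- qpfs_rank(M)
  expect_equal(sum(r$scores), 1, tolerance = 1e-6)
  expect_true(all(r$scores >= -1e-9))
  expect_true(informative_above_noise(r))
  # 5-feature instance: objective matches the exact KKT-enumeration oracle
  M5 <- feature_matrix(canonical_table()[c(1:3, 6, 7, 11)])
  r5 <- qpfs_rank(M5)
  Q <- pcgfusion:::feature_mi_matrix(M5)
  F_ <- apply(M5$values, 2, mutual_information, y = M5$labels)
  alpha <- attr(r5, "alpha")
  expect_equal(alpha, mean(Q) / (mean(Q) + mean(F_)))
  oracle <- qpfs_oracle(Q, F_, alpha)
  expect_lt(abs(attr(r5, "objective") - oracle$objective), 1e-6)
  # uncorrelated-features limit: scaled-identity Q ranks by relevance
  w_id <- local({
    p <- 4; Qi <- diag(p) * 0.5
    Fv <- c(0.9, 0.2, 0.6, 0.4)
    a <- mean(Qi) / (mean(Qi) + mean(Fv))
    g <- function(w) 0.5 * (1 - a) * drop(t(w) %*% Qi %*% w) - a * sum(Fv * w)
    w <- rep(0.25, p)
    for (i in 1:20000) {
      w <- pcgfusion:::project_simplex(w - ((1 - a) * Qi %*% w - a * Fv) / 2)
    }
    order(-as.numeric(w))
  })
  expect_identical(w_id, order(-c(0.9, 0.2, 0.6, 0.4)))
})

test_that("MIC is high for functional label dependence and low under the null", {
  y <- factor(rep(letters[1:5], each = 100))
  mono <- exp(as.integer(y))               # noiseless monotone function
  expect_gt(mic_score(mono, y), 0.95)
  set.seed(9)
  expect_lt(mic_score(rnorm(500), y), 0.3)
  M <- feature_matrix(canonical_table())
  r <- mic_rank(M)
  expect_true(all(r$scores >= 0 & r$scores <= 1))
  expect_true(informative_above_noise(r))
})

test_that("tree importance ranking is normalized, deterministic, and sane", {
  set.seed(5)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  df <- data.frame(sep = as.integer(y) + rnorm(n, 0, 0.05),
                   n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), label = y)
  M <- feature_matrix(df)
  r <- tree_rank(M, seed = 4)
  expect_identical(r$order[1], 1L)
  expect_equal(sum(r$scores), 1, tolerance = 1e-9)
  expect_identical(tree_rank(M, seed = 4)$order, r$order)
})

test_that("RFECV eliminates noise first and returns a full permutation", {
  set.seed(5)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  df <- data.frame(sep = as.integer(y) + rnorm(n, 0, 0.05),
                   n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), label = y)
  M <- feature_matrix(df)
  r <- rfecv_rank(M, folds = 5, seed = 4)
  expect_setequal(r$order, seq_len(4))
  expect_identical(r$order[1], 1L)          # separator survives to the end
  expect_lte(attr(r, "cv_best_k"), 4)
  expect_gte(attr(r, "cv_best_k"), 1)
})

test_that("all six rankers return reproducible full permutations", {
  M <- feature_matrix(canonical_table(n = 250))
  p <- ncol(M$values)
  for (method in c("mrmr", "kcca_mrmr", "qpfs", "mic", "tree", "rfecv")) {
    r1 <- rank_features(M, method, seed = 3)
    r2 <- rank_features(M, method, seed = 3)
    expect_setequal(r1$order, seq_len(p))
    expect_identical(r1$order, r2$order)
  }
})

test_that("rankings export to CSV with rank, feature, score columns", {
  M <- feature_matrix(canonical_table(n = 100))
  r <- mrmr_rank(M)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking_csv(r, path)
  df <- read.csv(path)
  expect_identical(names(df), c("rank", "feature", "score"))
  expect_identical(df$feature, r$feature_names[r$order])
})
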