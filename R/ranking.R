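#' Assemble a feature matrix for ranking and classification
#'
#' Converts a feature table (as from [corpus_features()] or
#' [read_feature_table()]) into the matrix form the rankers and classifiers
#' consume. Missing values (e.g. reserve times for records whose
#' segmentation failed) are imputed with the column median and the affected
#' columns are recorded in `imputed`.
#'
#' @param df Data frame with a `label` column, optionally `id`, and numeric
#'   feature columns.
#' @return An object of class `feature_matrix`: list with `values` (n-by-p
#'   matrix), `labels` (factor), `feature_names`, `imputed`.
#' @export
feature_matrix <- function(df) {
  stopifnot(is.data.frame(df), "label" %in% names(df))
  fcols <- setdiff(names(df), c("id", "label"))
  values <- as.matrix(df[fcols])
  storage.mode(values) <- "double"
  labels <- factor(df$label)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need at least 2 classes with at least 2 members each")
  }
  imputed <- character(0)
  for (j in seq_len(ncol(values))) {
    na <- !is.finite(values[, j])
    if (any(na)) {
      values[na, j] <- stats::median(values[!na, j])
      imputed <- c(imputed, fcols[j])
    }
  }
  structure(list(values = values, labels = labels, feature_names = fcols,
                 imputed = imputed),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d x %d, %d classes>\n", nrow(x$values),
              ncol(x$values), nlevels(x$labels)))
  invisible(x)
}

# Equal-frequency discretization into at most `bins` bins.
discretize_ef <- function(x, bins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(factor(rep(1L, length(x))))
  cut(x, br, include.lowest = TRUE, labels = FALSE)
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual information between a feature and the class labels
#'
#' Plug-in estimate in nats. A continuous feature is first discretized into
#' `bins` equal-frequency bins; a factor/discrete input is used as-is.
#'
#' @param x Feature column (numeric) or discrete vector.
#' @param y Class labels.
#' @param bins Number of equal-frequency bins for continuous features.
#' @return Non-negative scalar (0 for a constant feature).
#' @export
mutual_information <- function(x, y, bins = 10L) {
  xd <- if (is.numeric(x) && length(unique(x)) > bins) {
    discretize_ef(x, bins)
  } else x
  mi_from_table(table(xd, y))
}

new_ranking <- function(method, order, scores, feature_names) {
  stopifnot(length(order) == length(feature_names))
  structure(list(method = method, order = order, scores = scores,
                 feature_names = feature_names),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result %s: %s ...>\n", x$method,
              paste(utils::head(x$feature_names[x$order], 5), collapse = " > ")))
  invisible(x)
}

# Descending order with ties broken by original column position.
order_desc_stable <- function(scores) order(-scores, seq_along(scores))

relevance_vector <- function(M, bins = 10L) {
  apply(M$values, 2, mutual_information, y = M$labels, bins = bins)
}

feature_mi_matrix <- function(M, bins = 10L) {
  p <- ncol(M$values)
  disc <- lapply(seq_len(p), function(j) discretize_ef(M$values[, j], bins))
  Q <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      Q[i, j] <- Q[j, i] <- mi_from_table(table(disc[[i]], disc[[j]]))
    }
  }
  Q
}

#' Rank features by minimum redundancy, maximum relevance (mRMR)
#'
#' Greedy forward ranking under the mutual-information difference criterion:
#' the first feature maximizes MI with the labels; each subsequent pick
#' maximizes `MI(f; y) - mean_{g in S} MI(f; g)` over the already-selected
#' set S. Ties are broken by original column order.
#'
#' @param M A [feature_matrix()].
#' @param bins Discretization bins for the MI estimates.
#' @return A `ranking_result` whose `scores` are the greedy criterion values
#'   at selection time.
#' @export
mrmr_rank <- function(M, bins = 10L) {
  p <- ncol(M$values)
  rel <- relevance_vector(M, bins)
  red <- feature_mi_matrix(M, bins)
  mrmr_greedy(rel, red, "mrmr", M$feature_names)
}

mrmr_greedy <- function(rel, red, method, feature_names, gate = NULL) {
  p <- length(rel)
  selected <- integer(0)
  scores <- numeric(p)
  remaining <- seq_len(p)
  while (length(remaining)) {
    crit <- vapply(remaining, function(f) {
      if (!length(selected)) return(rel[f])
      r <- red[f, selected]
      if (!is.null(gate)) r <- r * gate[f, selected]
      rel[f] - mean(r)
    }, numeric(1))
    pick <- remaining[order(-crit, remaining)[1]]
    scores[pick] <- max(crit)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  new_ranking(method, selected, scores, feature_names)
}

# Regularized kernel canonical correlation between the label-explained parts
# of two feature columns. Gaussian-kernel Gram matrices (median-distance
# bandwidth) are centred and projected onto the class-indicator subspace, so
# only variation shared THROUGH the labels contributes; the first canonical
# correlation of the regularized correlation operator is returned. Features
# whose class-conditional structure is flat give values near zero.
kcca_label_cor <- function(f, g, y, reg = 0.05, kernel_width = NULL,
                           max_n = 200L) {
  n <- length(y)
  idx <- if (n > max_n) unique(round(seq(1, n, length.out = max_n))) else seq_len(n)
  f <- f[idx]; g <- g[idx]; y <- droplevels(factor(y[idx]))
  m <- length(idx)
  gram <- function(v) {
    d2 <- outer(v, v, "-")^2
    w <- if (is.null(kernel_width)) sqrt(stats::median(d2[d2 > 0])) else kernel_width
    if (!is.finite(w) || w == 0) w <- 1
    exp(-d2 / (2 * w^2))
  }
  H <- diag(m) - 1 / m
  Yi <- stats::model.matrix(~ y - 1)
  P <- Yi %*% solve(crossprod(Yi)) %*% t(Yi)
  A <- P %*% H %*% gram(f) %*% H %*% P
  B <- P %*% H %*% gram(g) %*% H %*% P
  kap <- reg * m
  Mop <- solve(A + kap * diag(m), A) %*% solve(B + kap * diag(m), B)
  ev <- eigen(Mop, only.values = TRUE)$values
  rho2 <- max(0, Re(ev[1]))
  sqrt(min(rho2, 1))
}

#' mRMR with a kernel-canonical-correlation redundancy gate
#'
#' Like [mrmr_rank()], but the redundancy term between a candidate and an
#' already-selected feature only counts when the pair shares label-relevant
#' structure: the regularized kernel canonical correlation between their
#' class-conditional (label-explained) kernel components must exceed
#' `gate_threshold`, otherwise that pairwise redundancy is set to zero. Pairs
#' that are correlated only through label-independent noise are therefore
#' not penalized. Large `reg` shrinks every canonical correlation towards
#' zero and the ranking degenerates to relevance-only ordering.
#'
#' @param M A [feature_matrix()].
#' @param kernel_width Gaussian kernel bandwidth; `NULL` uses the median
#'   pairwise distance of each feature.
#' @param reg Regularization of the canonical correlation operator (scaled
#'   by the subsample size).
#' @param gate_threshold Canonical correlation below which redundancy is
#'   zeroed.
#' @param bins Discretization bins for the MI estimates.
#' @param max_n Deterministic subsample cap for the kernel computation.
#' @return A `ranking_result`.
#' @export
kcca_mrmr_rank <- function(M, kernel_width = NULL, reg = 0.05,
                           gate_threshold = 0.3, bins = 10L, max_n = 200L) {
  p <- ncol(M$values)
  rel <- relevance_vector(M, bins)
  red <- feature_mi_matrix(M, bins)
  gate <- matrix(1, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j) {
        rho <- kcca_label_cor(M$values[, i], M$values[, j], M$labels,
                              reg = reg, kernel_width = kernel_width,
                              max_n = max_n)
        gate[i, j] <- gate[j, i] <- as.numeric(rho >= gate_threshold)
      }
    }
  }
  mrmr_greedy(rel, red, "kcca_mrmr", M$feature_names, gate = gate)
}

# Euclidean projection of v onto the probability simplex (Duchi et al.).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

qpfs_objective <- function(w, Q, F_, alpha) {
  0.5 * (1 - alpha) * drop(t(w) %*% Q %*% w) - alpha * sum(F_ * w)
}

#' Quadratic programming feature selection (QPFS)
#'
#' Solves \deqn{\min_w \tfrac12 (1-\alpha) w^T Q w - \alpha F^T w
#'   \quad s.t.\; w \ge 0,\; \sum w = 1,}
#' where Q is the feature-feature mutual-information similarity matrix, F
#' the feature-label MI vector, and
#' \eqn{\alpha = \bar{Q} / (\bar{Q} + \bar{F})} balances redundancy against
#' relevance. Features are ranked by descending weight. The program is
#' solved by projected gradient descent on the simplex with a fixed
#' 1/Lipschitz step.
#'
#' @param M A [feature_matrix()].
#' @param bins Discretization bins for the MI estimates.
#' @param tol Convergence tolerance on the weight update.
#' @param max_iter Iteration cap.
#' @return A `ranking_result` with weights in `scores` and the solver state
#'   in attributes `alpha` and `objective`.
#' @export
qpfs_rank <- function(M, bins = 10L, tol = 1e-12, max_iter = 50000L) {
  Q <- feature_mi_matrix(M, bins)
  F_ <- relevance_vector(M, bins)
  alpha <- mean(Q) / (mean(Q) + mean(F_))
  p <- length(F_)
  L <- (1 - alpha) * max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values))
  if (L <= 0) L <- 1
  w <- rep(1 / p, p)
  for (it in seq_len(max_iter)) {
    g <- (1 - alpha) * drop(Q %*% w) - alpha * F_
    w_new <- project_simplex(w - g / L)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  if (it == max_iter && max(abs(w_new - w)) >= tol) {
    stop("QPFS projected gradient did not converge; alpha=", signif(alpha, 4))
  }
  rk <- new_ranking("qpfs", order_desc_stable(w), w, M$feature_names)
  attr(rk, "alpha") <- alpha
  attr(rk, "objective") <- qpfs_objective(w, Q, F_, alpha)
  rk
}

#' Rank features by the maximal information coefficient (MIC)
#'
#' Per-feature MIC against the class labels. The characteristic matrix is
#' explored over grids with at most `B = n^0.6` cells: the label axis is
#' partitioned on class-code boundaries (2 up to the number of classes,
#' equal-frequency groupings), and for each label partition the feature-axis
#' partition is optimized exactly by dynamic programming over clumps
#' (capped at `c_factor` times the allowed number of feature bins). MIC is
#' the maximum of normalized mutual information `I / log(min(kx, ky))` over
#' the explored grids and always lies in [0, 1].
#'
#' @param M A [feature_matrix()].
#' @param c_factor Clump-count multiplier of the MINE search.
#' @return A `ranking_result` with MIC values in `scores`.
#' @export
mic_rank <- function(M, c_factor = 15L) {
  scores <- apply(M$values, 2, mic_score, y = M$labels, c_factor = c_factor)
  new_ranking("mic", order_desc_stable(scores), scores, M$feature_names)
}

#' @rdname mic_rank
#' @param x Numeric feature.
#' @param y Class labels.
#' @export
mic_score <- function(x, y, c_factor = 15L) {
  y <- factor(y)
  n <- length(x)
  B <- max(4, floor(n^0.6))
  C <- nlevels(y)
  ord <- order(x, as.integer(y))
  yi <- as.integer(y)[ord]
  best <- 0
  for (ky in 2:max(2, C)) {
    yb <- group_labels_ef(yi, ky)
    kx_max <- max(2L, floor(B / ky))
    ii <- optimize_x_axis(yb, kx_max, c_factor)
    if (!length(ii)) next
    m <- ii / log(pmin(seq_along(ii) + 1L, ky))
    best <- max(best, m, na.rm = TRUE)
  }
  min(best, 1)
}

# Merge the (ordered) integer label codes into at most k equal-frequency
# groups, preserving code order.
group_labels_ef <- function(yi, k) {
  lev <- sort(unique(yi))
  if (length(lev) <= k) return(match(yi, lev))
  cnt <- table(factor(yi, levels = lev))
  target <- length(yi) / k
  grp <- integer(length(lev)); g <- 1L; acc <- 0
  for (i in seq_along(lev)) {
    if (acc >= target * g && g < k) g <- g + 1L
    grp[i] <- g
    acc <- acc + cnt[i]
  }
  grp[match(yi, lev)]
}

# Exact DP over clumps maximizing I(X-partition; Y) for every feature-axis
# bin count 2..kx_max, given points sorted by x with y-group codes `yb`.
# Returns the vector of optimal mutual informations (nats), index l-1 for l
# bins. A clump is a maximal run of points sharing a y-group; clumps are
# merged down to at most c_factor * kx_max superclumps.
optimize_x_axis <- function(yb, kx_max, c_factor = 15L) {
  n <- length(yb)
  r <- rle(yb)
  k <- length(r$lengths)
  cap <- max(2L, c_factor * kx_max)
  bnd <- cumsum(r$lengths)                    # clump end positions
  if (k > cap) {                              # superclumps: near-equipartition
    targets <- seq_len(cap) * n / cap
    sel <- vapply(targets, function(tt) bnd[which.min(abs(bnd - tt))], numeric(1))
    bnd <- sort(unique(c(sel, n)))
    k <- length(bnd)
  }
  C <- max(yb)
  # cumulative per-group counts at clump boundaries, row 0 = zeros
  cum <- matrix(0, k + 1L, C)
  pos <- 1L
  for (t in seq_len(k)) {
    seg <- yb[pos:bnd[t]]
    cnt <- tabulate(seg, nbins = C)
    cum[t + 1L, ] <- cum[t, ] + cnt
    pos <- bnd[t] + 1L
  }
  hy <- shannon_h(cum[k + 1L, ] / n)
  # w(s, t): contribution sum_j m_j log(m_j / m) of a bin covering clumps
  # (s, t]; J-DP maximizes sum over bins, and I = H(Y) + J / n.
  wfun <- function(svec, t) {
    mm <- cum[rep(t + 1L, length(svec)), , drop = FALSE] - cum[svec + 1L, , drop = FALSE]
    m <- rowSums(mm)
    out <- numeric(length(svec))
    for (j in seq_len(C)) {
      v <- mm[, j]
      nz <- v > 0
      out[nz] <- out[nz] + v[nz] * log(v[nz] / m[nz])
    }
    out
  }
  kx_max <- min(kx_max, k)
  if (kx_max < 2) return(numeric(0))
  # J[t, l]: best over partitions of first t clumps into l bins
  J <- matrix(-Inf, k, kx_max)
  J[, 1] <- vapply(seq_len(k), function(t) wfun(0L, t), numeric(1))
  for (l in 2:kx_max) {
    for (t in l:k) {
      s <- (l - 1L):(t - 1L)
      J[t, l] <- max(J[s, l - 1L] + wfun(s, t))
    }
  }
  hy + J[k, 2:kx_max] / n
}

#' Rank features by tree-ensemble importance
#'
#' Mean decrease in Gini impurity from a random forest of `n_trees`
#' randomized trees, normalized to sum to one. Deterministic given `seed`.
#'
#' @param M A [feature_matrix()].
#' @param n_trees Ensemble size.
#' @param seed Integer seed.
#' @return A `ranking_result` with normalized importances in `scores`.
#' @export
tree_rank <- function(M, n_trees = 100L, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fit <- randomForest::randomForest(x = M$values, y = M$labels, ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  new_ranking("tree", order_desc_stable(imp), unname(imp), M$feature_names)
}

#' Rank features by recursive feature elimination with cross-validation
#'
#' Repeatedly fits a random forest, drops the least important remaining
#' feature, and records the elimination order; the reversed order is the
#' ranking. The cross-validation stage then evaluates each top-k prefix by
#' stratified k-fold accuracy and reports the best (smallest on ties)
#' feature count in attribute `cv_best_k` (curve in `cv_curve`).
#'
#' @param M A [feature_matrix()].
#' @param folds CV folds.
#' @param seed Integer seed.
#' @param n_trees Ensemble size of the base estimator.
#' @return A `ranking_result`; `scores` hold the elimination step at which a
#'   feature was dropped (higher = survived longer).
#' @export
rfecv_rank <- function(M, folds = 10L, seed = 1L, n_trees = 100L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  p <- ncol(M$values)
  remaining <- seq_len(p)
  dropped <- integer(0)
  while (length(remaining) > 1) {
    fit <- randomForest::randomForest(x = M$values[, remaining, drop = FALSE],
                                      y = M$labels, ntree = n_trees)
    imp <- fit$importance[, "MeanDecreaseGini"]
    worst <- remaining[order(imp, -seq_along(imp))[1]]
    dropped <- c(dropped, worst)
    remaining <- setdiff(remaining, worst)
  }
  ord <- rev(c(dropped, remaining))
  scores <- numeric(p)
  scores[ord] <- p:1
  rk <- new_ranking("rfecv", ord, scores, M$feature_names)
  cv <- vapply(seq_len(p), function(k) {
    sub <- M
    sub$values <- M$values[, ord[seq_len(k)], drop = FALSE]
    sub$feature_names <- M$feature_names[ord[seq_len(k)]]
    stratified_kfold_cv(sub, "rf", folds = folds, seed = seed)$accuracy
  }, numeric(1))
  attr(rk, "cv_curve") <- cv
  attr(rk, "cv_best_k") <- which.max(cv)
  rk
}

#' Write a ranking to CSV
#' @param ranking A `ranking_result`.
#' @param path Output path.
#' @export
write_ranking_csv <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order),
                   feature = ranking$feature_names[ranking$order],
                   score = ranking$scores[ranking$order])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
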