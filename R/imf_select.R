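#' Pearson correlation between a signal and one component
#'
#' The product-moment correlation \eqn{Corr_i} used to score how much of the
#' original signal an IMF layer carries.
#'
#' @param s,c Equal-length numeric vectors, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
corr_coef <- function(s, c) {
  if (length(s) != length(c)) stop("signals must have equal length")
  if (length(s) < 2) stop("need at least 2 samples")
  if (stats::sd(s) == 0 || stats::sd(c) == 0) {
    stop("correlation undefined for a constant signal")
  }
  stats::cor(s, c)
}

#' Root mean square error between a signal and one component
#'
#' \eqn{RMSE_i = \sqrt{\sum_j (s_j - c_j)^2 / N}}; small values mean the
#' component is close to the original signal.
#'
#' @param s,c Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(s, c) {
  if (length(s) != length(c)) stop("signals must have equal length")
  sqrt(mean((s - c)^2))
}

new_selection_report <- function(corr, rmse, hd, lambda_thr, delta_thr,
                                 epsilon_thr, selected, method) {
  structure(list(corr = corr, rmse = rmse, hd = hd,
                 lambda_thr = lambda_thr, delta_thr = delta_thr,
                 epsilon_thr = epsilon_thr, selected = sort(unname(selected)),
                 method = method),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report method=%s selected={%s}>\n",
              x$method, paste(x$selected, collapse = ",")))
  invisible(x)
}

#' Select IMFs by joint correlation and RMSE thresholds
#'
#' Scores each IMF layer against the original signal by Pearson correlation
#' and RMSE, forms the adaptive thresholds
#' \eqn{\lambda = \sum_{i=1}^{L-1} Corr_i / (L-1)} and
#' \eqn{\delta = \sum_{i=1}^{L-1} RMSE_i / (L-1)} (L the number of IMFs), and
#' keeps every layer with \eqn{Corr_i \ge \lambda} and \eqn{RMSE_i \le \delta}.
#' An empty selection falls back to the layer with maximal correlation.
#'
#' @param s Original signal.
#' @param imfs An `imf_set` from [emd_decompose()] with at least 2 IMFs.
#' @return A `selection_report`.
#' @export
corr_rmse_select <- function(s, imfs) {
  L <- n_imfs(imfs)
  if (L < 2) stop("corr/RMSE selection needs at least 2 IMFs")
  corr <- apply(imfs$imfs, 2, function(ci) corr_coef(s, ci))
  rms <- apply(imfs$imfs, 2, function(ci) rmse(s, ci))
  lambda <- sum(corr[seq_len(L - 1)]) / (L - 1)
  delta <- sum(rms[seq_len(L - 1)]) / (L - 1)
  sel <- which(corr >= lambda & rms <= delta)
  if (!length(sel)) {
    sel <- which.max(corr)
    message("empty corr/RMSE selection; falling back to the most correlated IMF")
  }
  new_selection_report(corr, rms, rep(NA_real_, L), lambda, delta, NA_real_,
                       sel, "corr_rmse")
}

#' Bidirectional Hausdorff distance between two point sets
#'
#' \eqn{H(A,B) = \max[h(A,B), h(B,A)]} with the directed distance
#' \eqn{h(A,B) = \max_{a \in A} \min_{b \in B} \|a - b\|} under the Euclidean
#' norm. Point sets are matrices with one row per point (1 or 2 columns); a
#' plain numeric vector is treated as a 1-D point set.
#'
#' @param a,b Nonempty point sets.
#' @return Non-negative scalar; zero iff the sets are equal.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as_point_set(a); b <- as_point_set(b)
  if (!nrow(a) || !nrow(b)) stop("point sets must be nonempty")
  if (ncol(a) != ncol(b)) stop("point sets must share a dimension")
  max(directed_hausdorff_cpp(a[, 1], a[, ncol(a)] * (ncol(a) > 1),
                             b[, 1], b[, ncol(b)] * (ncol(b) > 1)),
      directed_hausdorff_cpp(b[, 1], b[, ncol(b)] * (ncol(b) > 1),
                             a[, 1], a[, ncol(a)] * (ncol(a) > 1)))
}

as_point_set <- function(p) {
  if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 1)
}

# Embed a signal as a point set for Hausdorff scoring. In the default
# "time_amplitude_2d" space each sample j maps to (j/fs, x_j / scale) —
# `scale` is the peak of the ORIGINAL signal, shared between the signal and
# every IMF so that amplitudes stay comparable; "amplitude_1d" drops the
# time axis. Long signals are decimated by stride to at most max_points
# points: the distance varies smoothly under decimation and exact O(nm)
# evaluation of 10^4-point sets is needless for a threshold rule.
signal_point_set <- function(x, fs, hd_space = c("time_amplitude_2d", "amplitude_1d"),
                             max_points = 2000L, scale = max(abs(x))) {
  hd_space <- match.arg(hd_space)
  n <- length(x)
  idx <- if (n > max_points) {
    unique(round(seq(1L, n, length.out = max_points)))
  } else seq_len(n)
  xv <- x[idx]
  if (scale > 0) xv <- xv / scale
  if (hd_space == "amplitude_1d") {
    matrix(xv, ncol = 1)
  } else {
    cbind((idx - 1) / fs, xv)
  }
}

# Hausdorff distance of every IMF layer (first k_max at most) to the signal.
imf_hd_scores <- function(s, imfs, fs, k_max = n_imfs(imfs),
                          hd_space = "time_amplitude_2d", max_points = 2000L) {
  K <- min(k_max, n_imfs(imfs))
  sc <- max(abs(s))
  ps <- signal_point_set(s, fs, hd_space, max_points, scale = sc)
  vapply(seq_len(K), function(i) {
    hausdorff_distance(ps, signal_point_set(imfs$imfs[, i], fs, hd_space,
                                            max_points, scale = sc))
  }, numeric(1))
}

#' Select IMFs by Hausdorff distance
#'
#' Computes the Hausdorff distance \eqn{HD_i} between each IMF layer and the
#' original signal (both embedded as normalized time-amplitude point sets)
#' and keeps layers with small distance.
#'
#' Method `"adaptive_hd"` restricts attention to the first
#' \eqn{K = \min(7, L)} layers and uses the adaptive threshold
#' \eqn{\varepsilon = \sum_{i=1}^{K} HD_i / 7}; a layer \eqn{i \le K} is kept
#' when \eqn{HD_i \le \varepsilon}. Method `"hd_fixed"` scores all L layers
#' and keeps those at or below the mean distance. An empty selection falls
#' back to the layer with minimal distance.
#'
#' @param s Original signal.
#' @param imfs An `imf_set` with at least 1 IMF.
#' @param fs Sampling rate in Hz (sets the time scale of the embedding).
#' @param method `"adaptive_hd"` (first-seven-layer adaptive threshold) or
#'   `"hd_fixed"` (mean threshold over all layers).
#' @param hd_space Point-set embedding, `"time_amplitude_2d"` (default) or
#'   `"amplitude_1d"`.
#' @param max_points Decimation cap for the embedded point sets.
#' @return A `selection_report`.
#' @export
hd_select <- function(s, imfs, fs, method = c("adaptive_hd", "hd_fixed"),
                      hd_space = "time_amplitude_2d", max_points = 2000L) {
  method <- match.arg(method)
  L <- n_imfs(imfs)
  if (L < 1) stop("Hausdorff selection needs at least 1 IMF")
  K <- if (method == "adaptive_hd") min(7L, L) else L
  hd <- imf_hd_scores(s, imfs, fs, K, hd_space, max_points)
  eps <- if (method == "adaptive_hd") sum(hd) / 7 else mean(hd)
  sel <- which(hd <= eps)
  if (!length(sel)) {
    sel <- which.min(hd)
    message("empty Hausdorff selection; falling back to the closest IMF")
  }
  new_selection_report(rep(NA_real_, L)[seq_len(L)], rep(NA_real_, L),
                       c(hd, rep(NA_real_, L - K)), NA_real_, NA_real_, eps,
                       sel, method)
}

#' Apply the adaptive Hausdorff threshold to precomputed distances
#'
#' Threshold arithmetic only: given per-layer distances, form
#' \eqn{\varepsilon = \sum_{i=1}^{\min(7, L)} HD_i / 7} and select the layers
#' at or below it. Exposed separately so the rule can be audited on fixed
#' score vectors.
#'
#' @param hd Numeric vector of per-layer Hausdorff distances.
#' @return List with `epsilon_thr` and `selected`.
#' @export
adaptive_hd_threshold <- function(hd) {
  K <- min(7L, length(hd))
  eps <- sum(hd[seq_len(K)]) / 7
  list(epsilon_thr = eps, selected = which(hd[seq_len(K)] <= eps))
}

#' Reconstruct a sub-signal from selected IMFs
#'
#' Elementwise sum of the selected IMF layers; the residue is excluded unless
#' `include_residue = TRUE`.
#'
#' @param imfs An `imf_set`.
#' @param selected Nonempty vector of 1-based IMF indices.
#' @param include_residue Add the residue to the sum.
#' @return Numeric vector the length of the source signal.
#' @export
reconstruct_signal <- function(imfs, selected, include_residue = FALSE) {
  if (!length(selected)) stop("cannot reconstruct from an empty selection")
  if (any(selected < 1 | selected > n_imfs(imfs))) stop("invalid IMF indices")
  out <- rowSums(imfs$imfs[, selected, drop = FALSE])
  if (include_residue) out <- out + imfs$residue
  out
}

#' Serialize a selection report to JSON
#' @param report A `selection_report`.
#' @param path Output path.
#' @export
write_selection_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
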