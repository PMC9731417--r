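#' Denoise one signal by EMD reconstruction
#'
#' Decomposes the signal, screens IMF layers by the chosen rule, and sums
#' the selected layers. Method `"none"` returns the signal unchanged. When
#' the decomposition yields too few IMFs for the rule (fewer than 2), the
#' original signal is returned with a message.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param method `"adaptive_hd"`, `"corr_rmse"`, `"hd_fixed"` or `"none"`.
#' @param cfg A [sift_config()].
#' @param hd_max_points Point-set decimation cap for the Hausdorff rules.
#' @return Numeric vector; the selection report (if any) is attached as
#'   attribute `"selection"`.
#' @export
reconstruct_record <- function(x, fs,
                               method = c("adaptive_hd", "corr_rmse",
                                          "hd_fixed", "none"),
                               cfg = sift_config(), hd_max_points = 1000L) {
  method <- match.arg(method)
  if (method == "none") return(x)
  imfs <- emd_decompose(x, cfg)
  if (n_imfs(imfs) < 2) {
    message("too few IMFs for selection; returning the original signal")
    return(x)
  }
  report <- switch(method,
    corr_rmse = corr_rmse_select(x, imfs),
    adaptive_hd = hd_select(x, imfs, fs, "adaptive_hd",
                            max_points = hd_max_points),
    hd_fixed = hd_select(x, imfs, fs, "hd_fixed", max_points = hd_max_points))
  structure(reconstruct_signal(imfs, report$selected), selection = report)
}

#' Extract a feature table from a corpus of recordings
#'
#' Runs the full preprocessing and feature stage on every record: EMD
#' reconstruction under the chosen screening rule, S1/S2 segmentation of the
#' reconstructed signal for the cardiac reserve times, and the fused feature
#' vector. Records whose segmentation fails get `NA` reserve times, later
#' imputed with the column median by [feature_matrix()].
#'
#' @param records List of `pcg_record` objects (e.g. from [synth_corpus()]
#'   or [load_record()]).
#' @param method IMF screening rule; see [reconstruct_record()].
#' @param include_reserve Include the four reserve-time features.
#' @param cfg A [sift_config()].
#' @param hd_max_points Point-set decimation cap for the Hausdorff rules.
#' @return Data frame with columns `id`, `label`, and the features in
#'   [feature_names()] order.
#' @export
corpus_features <- function(records, method = "adaptive_hd",
                            include_reserve = TRUE, cfg = sift_config(),
                            hd_max_points = 1000L) {
  rows <- lapply(records, function(rec) {
    y <- reconstruct_record(rec$samples, rec$fs, method, cfg, hd_max_points)
    fv <- extract_features(as.numeric(y), rec$fs,
                           include_reserve = include_reserve)
    c(list(id = rec$id, label = rec$label), as.list(fv))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Run one ranked, incremental classification experiment
#'
#' Convenience wrapper: feature table to [feature_matrix()], ranking by the
#' requested method, then [incremental_curve()].
#'
#' @param features Feature table (data frame with `label` column).
#' @param ranker One of `"mrmr"`, `"kcca_mrmr"`, `"qpfs"`, `"mic"`,
#'   `"tree"`, `"rfecv"`.
#' @param classifier `"rf"`, `"knn"` or `"dt"`.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return A `cv_result`.
#' @export
evaluate_features <- function(features, ranker = "tree", classifier = "rf",
                              folds = 10L, seed = 1L) {
  M <- feature_matrix(features)
  ranking <- rank_features(M, ranker, seed = seed)
  incremental_curve(M, ranking, classifier, folds = folds, seed = seed)
}

#' Dispatch to one of the six ranking methods
#'
#' @param M A [feature_matrix()].
#' @param method Ranking method name.
#' @param seed Integer seed (used by the randomized methods).
#' @return A `ranking_result`.
#' @export
rank_features <- function(M, method = c("tree", "mrmr", "kcca_mrmr", "qpfs",
                                        "mic", "rfecv"), seed = 1L) {
  switch(match.arg(method),
         mrmr = mrmr_rank(M),
         kcca_mrmr = kcca_mrmr_rank(M),
         qpfs = qpfs_rank(M),
         mic = mic_rank(M),
         tree = tree_rank(M, seed = seed),
         rfecv = rfecv_rank(M, seed = seed))
}
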