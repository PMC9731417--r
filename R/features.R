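#' Canonical feature names
#'
#' The 40 fused features in canonical table order: four cardiac reserve
#' times, 21 time-domain statistics, then entropy, nonlinear and spectral /
#' instantaneous descriptors.
#'
#' @param include_reserve Include the four reserve-time features `T1`, `T2`,
#'   `T11`, `T12` (40 features) or drop them (36).
#' @return Character vector of feature names.
#' @export
feature_names <- function(include_reserve = TRUE) {
  nm <- c("T1", "T2", "T11", "T12",
          "mean", "mean_square", "max", "min", "variance", "std", "rms",
          "peak_to_peak", "root_square_amplitude", "skewness", "kurtosis",
          "form_factor", "crest_factor", "impulse_factor", "margin_factor",
          "hjorth_mobility", "hjorth_complexity", "q1", "q2", "q3", "iqr",
          "energy_entropy", "sample_entropy", "approximate_entropy",
          "shannon_entropy", "mspe", "exponential_entropy",
          "mean_square_frequency", "centroid_frequency", "rms_frequency",
          "frequency_std", "inst_energy_maxmin_dev", "inst_energy_median",
          "inst_energy_mean", "inst_freq_median", "inst_freq_mean")
  if (include_reserve) nm else setdiff(nm, c("T1", "T2", "T11", "T12"))
}

#' Time-domain features
#'
#' The 21 time-domain statistics: population moments (mean, mean square,
#' variance, standard deviation, skewness \eqn{\mu_3/\sigma^3}, kurtosis
#' \eqn{\mu_4/\sigma^4}, non-excess), amplitude statistics (max, min, RMS,
#' peak-to-peak, root-square amplitude \eqn{(\frac{1}{N}\sum\sqrt{|x_i|})^2}),
#' dimensionless shape factors (form = RMS / mean absolute value; crest,
#' impulse and margin factors all use the peak-to-peak value
#' \eqn{X_{peak} = \max - \min} in the numerator), Hjorth mobility and
#' complexity, and quartiles with linear interpolation (type 7).
#'
#' @param x Non-constant numeric signal of length >= 4.
#' @return Named list of 21 reals.
#' @export
time_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  mu <- mean(x)
  msv <- mean(x^2)
  vr <- mean((x - mu)^2)
  if (vr == 0) stop("degenerate input: constant signal has undefined shape factors")
  sd_ <- sqrt(vr)
  rms_ <- sqrt(msv)
  mx <- max(x); mn <- min(x)
  p2p <- mx - mn
  abs_mean <- mean(abs(x))
  xrm <- mean(sqrt(abs(x)))^2
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- mean((d1 - mean(d1))^2)
  v2 <- mean((d2 - mean(d2))^2)
  mob <- sqrt(v1 / vr)
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(mean = mu, mean_square = msv, max = mx, min = mn, variance = vr,
       std = sd_, rms = rms_, peak_to_peak = p2p, root_square_amplitude = xrm,
       skewness = mean((x - mu)^3) / sd_^3, kurtosis = mean((x - mu)^4) / vr^2,
       form_factor = rms_ / abs_mean, crest_factor = p2p / rms_,
       impulse_factor = p2p / abs_mean, margin_factor = p2p / xrm,
       hjorth_mobility = mob,
       hjorth_complexity = sqrt(v2 / v1) / mob,
       q1 = q[1], q2 = q[2], q3 = q[3], iqr = q[3] - q[1])
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# Per-frame energy fractions (20 ms frames, no overlap).
frame_energy_fractions <- function(x, fs, frame_s = 0.02) {
  frame <- max(2L, round(frame_s * fs))
  nf <- length(x) %/% frame
  if (nf < 1) nf <- 1L
  e <- vapply(seq_len(nf), function(k) {
    sum(x[((k - 1) * frame + 1):min(k * frame, length(x))]^2)
  }, numeric(1))
  tot <- sum(e)
  if (tot == 0) stop("all-zero signal")
  e / tot
}

shannon_h <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Frequency-domain features
#'
#' Eleven descriptors from the one-sided DFT magnitude spectrum `P(f)` and
#' the analytic signal: centroid (centre-of-gravity) frequency
#' \eqn{\sum f P / \sum P}, mean-square frequency \eqn{\sum f^2 P / \sum P},
#' RMS frequency (its square root), frequency standard deviation
#' \eqn{\sqrt{\sum (f - f_c)^2 P / \sum P}}; spectral Shannon entropy of the
#' normalized magnitude distribution and energy entropy of 20 ms frame
#' energy fractions (both in nats); and from the squared analytic envelope
#' (instantaneous energy) its max-min deviation, median and mean, plus the
#' median and mean instantaneous frequency (unwrapped phase differentiated
#' by central differences, negative values clipped to 0).
#'
#' @param x Numeric signal of length >= 16, not all zero.
#' @param fs Sampling rate in Hz.
#' @return Named list of 11 reals.
#' @export
frequency_features <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 16)
  if (max(abs(x)) == 0) stop("all-zero signal")
  nb <- n %/% 2 + 1
  P <- Mod(stats::fft(x))[seq_len(nb)]
  f <- (seq_len(nb) - 1) * fs / n
  w <- P / sum(P)
  fc <- sum(f * w)
  msf <- sum(f^2 * w)
  z <- analytic_signal(x)
  env2 <- Mod(z)^2
  ph <- unwrap_phase(Arg(z))
  fi <- (ph[3:n] - ph[1:(n - 2)]) / (2 / fs) / (2 * pi)
  fi <- pmax(fi, 0)
  list(energy_entropy = shannon_h(frame_energy_fractions(x, fs)),
       shannon_entropy = shannon_h(w),
       mean_square_frequency = msf,
       centroid_frequency = fc,
       rms_frequency = sqrt(msf),
       frequency_std = sqrt(sum((f - fc)^2 * w)),
       inst_energy_maxmin_dev = max(env2) - min(env2),
       inst_energy_median = stats::median(env2),
       inst_energy_mean = mean(env2),
       inst_freq_median = stats::median(fi),
       inst_freq_mean = mean(fi))
}

#' Permutation entropy of ordinal patterns
#'
#' Shannon entropy (normalized to `[0, 1]` by `log(order!)`) of the
#' distribution of ordinal patterns of the given order and delay. Ties are
#' broken by position (first occurrence ranks lower).
#'
#' @param x Numeric signal.
#' @param order Embedding dimension (pattern length).
#' @param delay Lag between pattern elements.
#' @return Scalar in `[0, 1]`; 0 for a strictly monotone signal.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x) - (order - 1L) * delay
  if (n < 1) return(0)
  emb <- sapply(seq_len(order), function(k) x[(k - 1L) * delay + seq_len(n)])
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1)
  pat <- apply(emb, 1, function(v) paste(order(v), collapse = ""))
  p <- table(pat) / n
  h <- shannon_h(as.numeric(p))
  h / log(factorial(order))
}

coarse_grain <- function(x, scale) {
  nf <- length(x) %/% scale
  if (nf < 1) return(x)
  colMeans(matrix(x[seq_len(nf * scale)], nrow = scale))
}

#' Nonlinear (entropy) features
#'
#' Four complexity measures of the signal: sample entropy and approximate
#' entropy (both with embedding dimension m = 2 and tolerance r = 0.2 times
#' the standard deviation), multiscale permutation entropy (order 3, delay
#' 1, coarse-graining scales 1–5, averaged), and the Pal–Pal exponential
#' entropy \eqn{\sum_i p_i e^{1 - p_i} - 1} of the 20 ms frame-energy
#' distribution. Sample and approximate entropy are evaluated on the signal
#' decimated to at most `max_n` samples; the O(N^2) template matching gains
#' nothing from longer records at this tolerance.
#'
#' @param x Numeric signal of length >= 100.
#' @param fs Sampling rate in Hz (frame length of the exponential entropy).
#' @param max_n Decimation cap for sample/approximate entropy.
#' @return Named list of 4 reals. A constant signal yields all zeros with a
#'   warning.
#' @export
nonlinear_features <- function(x, fs = PIPELINE_FS, max_n = 2000L) {
  stopifnot(length(x) >= 100)
  if (stats::sd(x) == 0) {
    warning("constant signal: entropies defined as 0")
    return(list(sample_entropy = 0, approximate_entropy = 0, mspe = 0,
                exponential_entropy = 0))
  }
  xd <- if (length(x) > max_n) {
    x[unique(round(seq(1, length(x), length.out = max_n)))]
  } else x
  r <- 0.2 * stats::sd(xd)
  cnt <- sampen_counts_cpp(xd, 2L, r)
  samp <- if (cnt[1] > 0 && cnt[2] > 0) -log(cnt[1] / cnt[2]) else 0
  apen <- apen_phi_cpp(xd, 2L, r) - apen_phi_cpp(xd, 3L, r)
  mspe <- mean(vapply(1:5, function(s) {
    permutation_entropy(coarse_grain(x, s), order = 3L, delay = 1L)
  }, numeric(1)))
  p <- frame_energy_fractions(x, fs)
  list(sample_entropy = samp, approximate_entropy = apen, mspe = mspe,
       exponential_entropy = sum(p * exp(1 - p)) - 1)
}

#' Extract the fused feature vector
#'
#' Assembles the 40-feature fused vector (or the 36-feature variant without
#' the cardiac reserve times) from a signal: [time_features()],
#' [frequency_features()], [nonlinear_features()], and — when
#' `include_reserve = TRUE` — [reserve_times()] from `seg`. If segmentation
#' is absent or failed the reserve features are returned as `NA` so that a
#' corpus-level step can impute them (see [corpus_features()]).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param seg Optional `cycle_segmentation`; when `NULL` and
#'   `include_reserve = TRUE`, segmentation is attempted internally.
#' @param include_reserve Include `T1`, `T2`, `T11`, `T12`.
#' @return Named numeric vector in [feature_names()] order.
#' @export
extract_features <- function(x, fs, seg = NULL, include_reserve = TRUE) {
  vals <- c(unlist(time_features(x)), unlist(frequency_features(x, fs)),
            unlist(nonlinear_features(x, fs)))
  if (include_reserve) {
    rt <- c(T1 = NA_real_, T2 = NA_real_, T11 = NA_real_, T12 = NA_real_)
    if (is.null(seg)) {
      seg <- tryCatch(segment_pcg(x, fs), error = function(e) NULL)
    }
    if (!is.null(seg)) {
      rtv <- tryCatch(reserve_times(seg), error = function(e) NULL)
      if (!is.null(rtv)) rt <- unlist(rtv)
    }
    vals <- c(rt, vals)
  }
  vals[feature_names(include_reserve)]
}
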