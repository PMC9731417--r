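# Shared fixtures, all generated in code.

pipeline_fs <- 2205

two_tone <- function(duration = 1, fs = pipeline_fs) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  list(t = t, hi = sin(2 * pi * 300 * t), lo = sin(2 * pi * 30 * t),
       x = sin(2 * pi * 300 * t) + sin(2 * pi * 30 * t))
}

# Canonical ranking table: 3 informative features (f1, f2, f3), 2 near-exact
# redundant copies (f4 = f1, f5 = f2), 5 pure-noise features; balanced
# 5-class labels.
canonical_table <- function(n = 500, seed = 11) {
  set.seed(seed)
  y <- factor(rep(c("a", "b", "c", "d", "e"), each = n / 5))
  mu <- as.integer(y)
  f1 <- mu + rnorm(n, 0, 0.4)
  f2 <- -2 * mu + rnorm(n, 0, 0.5)
  f3 <- (mu %% 2) + rnorm(n, 0, 0.3)
  data.frame(f1 = f1, f2 = f2, f3 = f3,
             f4 = f1 + rnorm(n, 0, 0.01), f5 = f2 + rnorm(n, 0, 0.01),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n),
             n5 = rnorm(n), label = y)
}

# TRUE iff, for each informative group, at least one representative
# ({f1,f4}, {f2,f5}, {f3}) ranks above every noise feature.
informative_above_noise <- function(ranking) {
  nm <- ranking$feature_names[ranking$order]
  pos <- function(f) which(nm == f)
  worst_noise <- min(vapply(paste0("n", 1:5), pos, numeric(1)))
  all(c(min(pos("f1"), pos("f4")), min(pos("f2"), pos("f5")), pos("f3")) <
        worst_noise)
}

# Brute-force directed/bidirectional Hausdorff oracle, O(nm) outer products.
hausdorff_oracle <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2
  if (ncol(a) > 1) d2 <- d2 + outer(a[, 2], b[, 2], "-")^2
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}

# Exact QPFS oracle for small p: enumerate KKT support sets of the simplex-
# constrained QP and return the best feasible solution.
qpfs_oracle <- function(Q, F_, alpha) {
  p <- length(F_)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    k <- length(S)
    A <- rbind(cbind((1 - alpha) * Q[S, S, drop = FALSE], -1),
               c(rep(1, k), 0))
    rhs <- c(alpha * F_[S], 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w_S <- sol[seq_len(k)]
    if (any(w_S < -1e-9)) next
    w <- numeric(p); w[S] <- pmax(w_S, 0); w <- w / sum(w)
    obj <- 0.5 * (1 - alpha) * drop(t(w) %*% Q %*% w) - alpha * sum(F_ * w)
    if (obj < best_obj) { best_obj <- obj; best <- w }
  }
  list(w = best, objective = best_obj)
}

# Independent brute-force time-domain feature formulas: direct sums and
# sort-based quartiles.
time_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  srt <- sort(x)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, n)] - srt[lo])
  }
  rms <- sqrt(sum(x^2) / n)
  p2p <- srt[n] - srt[1]
  am <- sum(abs(x)) / n
  xrm <- (sum(sqrt(abs(x))) / n)^2
  d1 <- x[-1] - x[-n]
  d2 <- d1[-1] - d1[-(n - 1)]
  vc <- function(v) sum((v - sum(v) / length(v))^2) / length(v)
  mob <- sqrt(vc(d1) / m2)
  c(mean = mu, mean_square = sum(x^2) / n, max = srt[n], min = srt[1],
    variance = m2, std = sqrt(m2), rms = rms, peak_to_peak = p2p,
    root_square_amplitude = xrm, skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2, form_factor = rms / am, crest_factor = p2p / rms,
    impulse_factor = p2p / am, margin_factor = p2p / xrm,
    hjorth_mobility = mob, hjorth_complexity = sqrt(vc(d2) / vc(d1)) / mob,
    q1 = qt(0.25), q2 = qt(0.5), q3 = qt(0.75), iqr = qt(0.75) - qt(0.25))
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
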