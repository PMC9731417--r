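#' Sifting configuration for empirical mode decomposition
#'
#' Bundles the numerical controls of the sifting loop. Sifting stops when the
#' Cauchy-type standard-deviation criterion
#' \eqn{SD = \sum (h_{k-1} - h_k)^2 / \sum h_{k-1}^2} falls below
#' `sd_threshold` and the two intrinsic-mode-function (IMF) restrictions hold
#' (extrema and zero-crossing counts differing by at most one, near-zero
#' envelope mean), or when `max_sifts` passes have been performed.
#'
#' @param sd_threshold Dimensionless sifting-stop ratio (default 0.2,
#'   Huang's classic recipe).
#' @param max_sifts Maximum sifting passes per IMF.
#' @param max_imfs Maximum number of IMFs extracted before the remainder is
#'   declared the residue.
#' @param boundary Envelope boundary handling; only `"mirror"` (reflect two
#'   extrema about each end) is implemented.
#' @return An object of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sifts = 50L, max_imfs = 15L,
                        boundary = "mirror") {
  stopifnot(sd_threshold > 0, max_sifts >= 1, max_imfs >= 1)
  boundary <- match.arg(boundary, "mirror")
  structure(list(sd_threshold = sd_threshold, max_sifts = as.integer(max_sifts),
                 max_imfs = as.integer(max_imfs), boundary = boundary),
            class = "sift_config")
}

# Local extrema by strict sign change of the first difference; runs of equal
# values (plateaus) contribute their midpoint sample.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(d[nz])
  chg <- which(s[-length(s)] != s[-1])
  if (!length(chg)) return(list(maxima = integer(0), minima = integer(0)))
  pos <- (nz[chg] + 1L + nz[chg + 1L]) %/% 2L
  up <- s[chg] > 0
  list(maxima = pos[up], minima = pos[!up])
}

# Zero crossings: strict sign changes after dropping exact zeros (an exact
# zero sample counts as one crossing).
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(sum(x == 0))
  sum(s[-1] != s[-length(s)]) + sum(x == 0)
}

# Cubic-spline envelope through the given extrema, mirror-extending up to two
# extrema beyond each end so the spline is supported on [1, n].
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  li <- 2L - idx[pmin(2L, k):1L]             # reflect about sample 1
  lv <- val[pmin(2L, k):1L]
  ri <- 2L * n - idx[k:max(1L, k - 1L)]      # reflect about sample n
  rv <- val[k:max(1L, k - 1L)]
  keep_l <- li < idx[1L]
  keep_r <- ri > idx[k]
  xs <- c(li[keep_l], idx, ri[keep_r])
  ys <- c(lv[keep_l], val, rv[keep_r])
  stats::spline(xs, ys, xout = seq_len(n), method = "natural")$y
}

#' Mean of the upper and lower spline envelopes
#'
#' Fits natural cubic splines through the local maxima (upper envelope) and
#' local minima (lower envelope) of `x`, with mirror boundary extension, and
#' returns their pointwise mean \eqn{m(t) = (e_1(t) + e_2(t)) / 2} — the
#' quantity subtracted at each sifting pass.
#'
#' @param x Numeric signal.
#' @return Numeric vector of `length(x)`, or `NULL` when the signal has fewer
#'   than two maxima or two minima (a monotone trend, treated as residue).
#' @export
envelope_mean <- function(x) {
  ext <- find_extrema(x)
  if (length(ext$maxima) < 2 || length(ext$minima) < 2) return(NULL)
  e1 <- spline_envelope(ext$maxima, x[ext$maxima], length(x))
  e2 <- spline_envelope(ext$minima, x[ext$minima], length(x))
  (e1 + e2) / 2
}

is_imf_shape <- function(h) {
  ext <- find_extrema(h)
  n_ext <- length(ext$maxima) + length(ext$minima)
  abs(n_ext - count_zero_crossings(h)) <= 1
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope mean from the working signal,
#' \eqn{h_k = h_{k-1} - m_{k-1}}, until the stop rule of [sift_config()] is
#' met. If `max_sifts` is reached first, the current component is returned
#' with a warning.
#'
#' @param x Numeric signal with at least two maxima and two minima.
#' @param cfg A [sift_config()].
#' @return The sifted component `h` (one IMF candidate), with the number of
#'   passes in attribute `"sifts"`.
#' @export
sift <- function(x, cfg = sift_config()) {
  h <- x
  for (k in seq_len(cfg$max_sifts)) {
    m <- envelope_mean(h)
    if (is.null(m)) break                      # degenerated to monotone
    h1 <- h - m
    denom <- sum(h^2)
    sd_k <- if (denom > 0) sum(m^2) / denom else 0
    h <- h1
    if (sd_k < cfg$sd_threshold && is_imf_shape(h)) {
      return(structure(h, sifts = k))
    }
  }
  if (!is_imf_shape(h)) {
    warning("sifting stopped at max_sifts before the IMF restrictions were met")
  }
  structure(h, sifts = cfg$max_sifts)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions `c_1, ..., c_n` plus a
#' monotone residue `r_n` such that `x == rowSums(imfs) + residue` exactly
#' (the residue is formed by successive subtraction). IMFs are ordered from
#' the fastest oscillation to the slowest.
#'
#' @param x Finite numeric signal.
#' @param cfg A [sift_config()].
#' @param source_id Identifier carried through for reporting.
#' @return An object of class `imf_set`: list with `imfs` (matrix, one column
#'   per IMF), `residue`, and `source_id`. A constant or monotone input gives
#'   zero IMFs and `residue = x`.
#' @export
emd_decompose <- function(x, cfg = sift_config(), source_id = "signal") {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  r <- x
  imfs <- list()
  while (length(imfs) < cfg$max_imfs) {
    ext <- find_extrema(r)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break  # monotone residue
    ci <- as.numeric(sift(r, cfg))
    if (!any(ci != 0)) break
    imfs[[length(imfs) + 1L]] <- ci
    r <- r - ci
  }
  m <- if (length(imfs)) do.call(cbind, imfs) else matrix(numeric(0), nrow = n, ncol = 0)
  colnames(m) <- if (ncol(m)) paste0("c", seq_len(ncol(m)))
  structure(list(imfs = m, residue = r, source_id = source_id), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set '%s': %d IMFs of length %d + residue>\n",
              x$source_id, ncol(x$imfs), length(x$residue)))
  invisible(x)
}

#' Number of IMFs in a decomposition
#' @param imfs An `imf_set`.
#' @return Integer count.
#' @export
n_imfs <- function(imfs) ncol(imfs$imfs)

#' Write an IMF set to CSV
#'
#' One column per IMF plus a `residue` column, for external plotting of the
#' decomposition layers.
#'
#' @param imfs An `imf_set`.
#' @param path Output file path.
#' @export
write_imf_csv <- function(imfs, path) {
  df <- as.data.frame(cbind(imfs$imfs, residue = imfs$residue))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
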