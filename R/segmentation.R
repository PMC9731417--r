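new_cycle_segmentation <- function(cycles, fs, all_s1_onsets = cycles$s1_start) {
  stopifnot(is.data.frame(cycles),
            all(c("s1_start", "s1_end", "s2_start", "s2_end") %in% names(cycles)))
  structure(list(cycles = cycles, fs = fs, s1_onsets = all_s1_onsets),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation: %d cycles @ %g Hz>\n", nrow(x$cycles), x$fs))
  invisible(x)
}

# Normalized average Shannon energy envelope of a band-passed signal,
# evaluated on 20 ms frames with 10 ms hop; returns frame centres (s) and
# envelope values.
shannon_envelope <- function(x, fs, frame_s = 0.02, hop_s = 0.01) {
  xb <- x / max(abs(x))
  frame <- max(2L, round(frame_s * fs))
  hop <- max(1L, round(hop_s * fs))
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  env <- vapply(starts, function(s0) {
    seg <- xb[s0:(s0 + frame - 1L)]
    e <- seg^2
    -mean(ifelse(e > 0, e * log(e), 0))
  }, numeric(1))
  list(t = (starts - 1 + frame / 2) / fs, env = env, hop_s = hop / fs)
}

#' Segment a phonocardiogram into cardiac cycles
#'
#' Envelope-based S1/S2 detection: band-pass 25–150 Hz, normalized average
#' Shannon energy envelope (20 ms frames, 10 ms hop), adaptive threshold at
#' mean + 0.5 SD of the envelope, burst extraction with a 50 ms minimum gap,
#' burst on/offsets refined to the 10%-of-peak envelope crossing, and S1/S2
#' assignment by the physiological rule that systole (S1 to S2) is shorter
#' than diastole (S2 to next S1).
#'
#' @param x Numeric signal containing at least two cardiac cycles.
#' @param fs Sampling rate in Hz.
#' @return A `cycle_segmentation` with one row per complete S1–S2 cycle and
#'   the full list of S1 onsets (for the cycle-period feature).
#' @export
segment_pcg <- function(x, fs) {
  stopifnot(length(x) > fs, max(abs(x)) > 0)
  bf <- signal::butter(4, c(25, 150) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  se <- shannon_envelope(xf, fs)
  # heart sounds stand far above the envelope floor; broadband noise peaks
  # at roughly twice its median and is rejected here
  if (max(se$env) / stats::median(se$env) < 4) {
    stop("segmentation failure: no prominent energy bursts")
  }
  thr <- mean(se$env) + 0.5 * stats::sd(se$env)
  above <- se$env > thr
  if (!any(above)) stop("segmentation failure: no energy bursts found")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bi <- which(r$values)
  bursts <- data.frame(i1 = starts[bi], i2 = ends[bi])
  # merge bursts separated by less than 50 ms
  if (nrow(bursts) > 1) {
    merged <- bursts[1, , drop = FALSE]
    for (k in 2:nrow(bursts)) {
      gap <- se$t[bursts$i1[k]] - se$t[merged$i2[nrow(merged)]]
      if (gap < 0.05) {
        merged$i2[nrow(merged)] <- bursts$i2[k]
      } else {
        merged <- rbind(merged, bursts[k, ])
      }
    }
    bursts <- merged
  }
  # refine on/offsets at sample resolution: walk out from the burst peak of
  # the smoothed analytic amplitude envelope to its 10%-of-peak crossings
  aenv <- Mod(analytic_signal(xf))
  ksm <- max(3L, round(0.005 * fs))           # 5 ms moving average
  aenv <- stats::filter(aenv, rep(1 / ksm, ksm), sides = 2)
  aenv[is.na(aenv)] <- 0
  n <- length(aenv)
  onset <- offset <- numeric(nrow(bursts))
  for (k in seq_len(nrow(bursts))) {
    a <- max(1L, round(se$t[bursts$i1[k]] * fs) - round(0.05 * fs))
    b <- min(n, round(se$t[bursts$i2[k]] * fs) + round(0.05 * fs))
    pk <- a - 1L + which.max(aenv[a:b])
    lev <- 0.1 * aenv[pk]
    i <- pk
    while (i > 1 && aenv[i - 1] > lev) i <- i - 1
    f <- if (i > 1) (aenv[i] - lev) / (aenv[i] - aenv[i - 1]) else 0
    onset[k] <- (i - 1 - f) / fs
    j <- pk
    while (j < n && aenv[j + 1] > lev) j <- j + 1
    f <- if (j < n) (aenv[j] - lev) / (aenv[j] - aenv[j + 1]) else 0
    offset[k] <- (j - 1 + f) / fs
  }
  # drop implausibly short or long bursts (heart sounds last ~0.03-0.25 s)
  w <- offset - onset
  ok <- w >= 0.03 & w <= 0.30
  onset <- onset[ok]; offset <- offset[ok]
  if (length(onset) < 3) stop("segmentation failure: too few plausible bursts")
  # S1/S2 assignment: the shorter inter-onset interval is systole (S1 -> S2)
  iv <- diff(onset)
  med_odd <- stats::median(iv[seq(1, length(iv), by = 2)])
  med_even <- if (length(iv) >= 2) {
    stats::median(iv[seq(2, length(iv), by = 2)])
  } else Inf
  first_is_s1 <- med_odd < med_even
  lab <- rep(c("S2", "S1"), length.out = length(onset))
  if (first_is_s1) lab <- rep(c("S1", "S2"), length.out = length(onset))
  s1_idx <- which(lab == "S1")
  cyc <- list()
  for (k in s1_idx) {
    if (k + 1 <= length(onset) && lab[k + 1] == "S2") {
      cyc[[length(cyc) + 1L]] <- data.frame(
        s1_start = onset[k], s1_end = offset[k],
        s2_start = onset[k + 1], s2_end = offset[k + 1])
    }
  }
  if (!length(cyc)) stop("segmentation failure: no complete S1-S2 cycle")
  cycles <- do.call(rbind, cyc)
  bad <- with(cycles, s1_start >= s1_end | s1_end >= s2_start | s2_start >= s2_end)
  cycles <- cycles[!bad, , drop = FALSE]
  if (!nrow(cycles)) stop("segmentation failure: inconsistent cycle boundaries")
  # sanity: cycle periods must look cardiac (30-200 bpm) and consistent
  s1_on <- onset[s1_idx]
  if (length(s1_on) >= 2) {
    per <- diff(s1_on)
    if (stats::median(per) < 0.3 || stats::median(per) > 2 ||
        (length(per) >= 2 && stats::sd(per) / mean(per) > 0.35)) {
      stop("segmentation failure: burst train is not cardiac-like")
    }
  }
  new_cycle_segmentation(cycles, fs, all_s1_onsets = s1_on)
}

#' Cardiac reserve times from a segmentation
#'
#' Four per-recording durations, averaged over detected cycles: `T1` the S1
#' width, `T2` the S2 width, `T12` the S1-onset to S2-onset interval within
#' a cycle, and `T11` the full cycle period (S1 onset to the next S1 onset).
#'
#' @param seg A `cycle_segmentation` with at least one complete cycle and at
#'   least two S1 onsets.
#' @return Named list with `T1`, `T2`, `T11`, `T12` in seconds.
#' @export
reserve_times <- function(seg) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  cyc <- seg$cycles
  if (!nrow(cyc)) stop("no complete cycles")
  if (length(seg$s1_onsets) < 2) stop("T11 undefined: need at least two S1 onsets")
  list(T1 = mean(cyc$s1_end - cyc$s1_start),
       T2 = mean(cyc$s2_end - cyc$s2_start),
       T11 = mean(diff(seg$s1_onsets)),
       T12 = mean(cyc$s2_start - cyc$s1_start))
}

#' Write cycle boundaries to CSV for visual QC
#' @param seg A `cycle_segmentation`.
#' @param path Output path.
#' @export
write_segmentation_csv <- function(seg, path) {
  utils::write.csv(seg$cycles, path, row.names = FALSE)
  invisible(path)
}
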