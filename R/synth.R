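#' Specification of one synthetic phonocardiogram
#'
#' Describes a heart-sound archetype: Gabor (Gaussian-windowed sinusoid)
#' bursts for the first and second heart sounds S1/S2, an optional murmur
#' (band-limited noise or a mid-systolic click), and additive white noise at
#' a chosen signal-to-noise ratio. The default burst frequencies (S1 near
#' 30–45 Hz, S2 near 50–70 Hz) reflect the concentration of heart-sound
#' energy in the low-frequency band. Burst width is defined as the interval
#' where the Gaussian envelope exceeds 10% of its peak, which is also the
#' ground-truth S1/S2 on/offset convention.
#'
#' @param class_name Label carried into the generated record.
#' @param heart_rate Beats per minute.
#' @param s1_freq,s2_freq Dominant burst frequencies in Hz.
#' @param s1_width,s2_width Burst widths in seconds (10%-envelope support).
#' @param systole_fraction Fraction of the cycle from S1 onset to S2 onset
#'   (strictly between 0 and 0.5).
#' @param murmur One of `"none"`, `"systolic"`, `"diastolic"`, `"click"`.
#' @param murmur_band Two-element frequency band in Hz for noise murmurs (or
#'   the click tone frequency range).
#' @param murmur_level Murmur amplitude relative to the S1 peak.
#' @param snr Signal-to-noise ratio in dB for the additive white noise;
#'   `Inf` disables noise.
#' @param duration Seconds.
#' @param fs Sampling rate in Hz (pipeline default 2205).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(class_name = "NHS", heart_rate = 75, s1_freq = 38,
                       s2_freq = 58, s1_width = 0.12, s2_width = 0.09,
                       systole_fraction = 0.38,
                       murmur = c("none", "systolic", "diastolic", "click"),
                       murmur_band = c(120, 400), murmur_level = 0.35,
                       snr = 15, duration = 2.5, fs = 2205) {
  murmur <- match.arg(murmur)
  stopifnot(heart_rate > 0, systole_fraction > 0, systole_fraction < 0.5,
            fs >= 2 * max(s1_freq, s2_freq, murmur_band), duration > 0,
            s1_width > 0, s2_width > 0)
  period <- 60 / heart_rate
  if (s1_width + s2_width >= systole_fraction * period ||
      s2_width >= (1 - systole_fraction) * period) {
    stop("infeasible spec: S1/S2 bursts would overlap")
  }
  structure(as.list(environment()), class = "synth_spec")
}

# Gabor burst centred at t0 whose Gaussian envelope is above 10% of its peak
# over exactly `width` seconds.
gabor_burst <- function(t, t0, width, freq, amp = 1) {
  sigma <- width / (2 * sqrt(2 * log(10)))
  amp * exp(-0.5 * ((t - t0) / sigma)^2) * sin(2 * pi * freq * (t - t0))
}

bandpass_noise <- function(n, fs, band, rng_n = n) {
  w <- pmin(pmax(band / (fs / 2), 1e-3), 0.999)
  bf <- signal::butter(3, w, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / max(abs(x), 1e-12)
}

#' Generate one synthetic phonocardiogram with ground truth
#'
#' Places S1 bursts at intervals of `60 / heart_rate` seconds starting 0.1 s
#' into the record, S2 bursts `systole_fraction` of a cycle later, overlays
#' the class murmur, and adds white Gaussian noise scaled to the requested
#' SNR (measured against the clean signal).
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return List with `record` (a `pcg_record`), `clean` (pre-noise signal)
#'   and `truth` (a `cycle_segmentation` of the generated S1/S2 boundaries).
#' @export
synth_pcg <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fs <- spec$fs
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / spec$heart_rate
  s1_on <- seq(0.1, spec$duration - spec$s1_width, by = period)
  s1_c <- s1_on + spec$s1_width / 2
  s2_on <- s1_on + spec$systole_fraction * period
  s2_c <- s2_on + spec$s2_width / 2
  keep2 <- s2_on + spec$s2_width <= spec$duration
  clean <- numeric(n)
  for (c1 in s1_c) clean <- clean + gabor_burst(t, c1, spec$s1_width, spec$s1_freq)
  for (c2 in s2_c[keep2]) {
    clean <- clean + gabor_burst(t, c2, spec$s2_width, spec$s2_freq, amp = 0.8)
  }
  if (spec$murmur != "none") {
    win <- numeric(n)
    for (k in seq_along(s1_on)) {
      if (spec$murmur %in% c("systolic", "click")) {
        a <- s1_on[k] + spec$s1_width; b <- s2_on[k]
      } else {                                   # diastolic: S2 end to next S1
        if (!keep2[k]) next
        a <- s2_on[k] + spec$s2_width
        b <- if (k < length(s1_on)) s1_on[k + 1] else spec$duration
      }
      if (b <= a) next
      if (spec$murmur == "click") {
        clean <- clean + gabor_burst(t, (a + b) / 2, 0.03,
                                     mean(spec$murmur_band),
                                     amp = spec$murmur_level * 2)
      } else {
        win <- win + (t >= a & t <= b) * sin(pi * pmin(pmax((t - a) / (b - a), 0), 1))
      }
    }
    if (spec$murmur %in% c("systolic", "diastolic")) {
      clean <- clean + spec$murmur_level * win * bandpass_noise(n, fs, spec$murmur_band)
    }
  }
  x <- clean
  if (is.finite(spec$snr)) {
    p_sig <- mean(clean^2)
    p_noise <- p_sig / 10^(spec$snr / 10)
    x <- clean + stats::rnorm(n, sd = sqrt(p_noise))
  }
  n_cyc <- sum(keep2)
  cycles <- data.frame(
    s1_start = s1_on[seq_len(n_cyc)],
    s1_end = s1_on[seq_len(n_cyc)] + spec$s1_width,
    s2_start = s2_on[seq_len(n_cyc)],
    s2_end = s2_on[seq_len(n_cyc)] + spec$s2_width
  )
  truth <- new_cycle_segmentation(cycles, fs, all_s1_onsets = s1_on)
  rec <- new_pcg_record(id = paste0(spec$class_name, "_", seed), samples = x,
                        fs = fs, label = spec$class_name)
  list(record = rec, clean = clean, truth = truth)
}

#' Default archetype specs for the five heart-sound classes
#'
#' Synthetic analogues of aortic stenosis (AS: mid-band systolic murmur),
#' mitral stenosis (MS: low-band diastolic murmur), mitral regurgitation
#' (MR: lower-band systolic murmur), mitral valve prolapse (MVP:
#' mid-systolic click) and normal heart sound (NHS: no murmur). No claim of
#' clinical realism — the archetypes exist so that every pipeline stage has
#' labelled, separable input with known ground truth.
#'
#' @param snr Signal-to-noise ratio in dB applied to every class.
#' @param duration Record duration in seconds.
#' @return Named list of [synth_spec()] objects.
#' @export
default_class_specs <- function(snr = 15, duration = 2.5) {
  list(
    AS  = synth_spec("AS", heart_rate = 80, murmur = "systolic",
                     murmur_band = c(150, 420), murmur_level = 0.7,
                     snr = snr, duration = duration),
    MS  = synth_spec("MS", heart_rate = 70, murmur = "diastolic",
                     murmur_band = c(40, 150), murmur_level = 0.55,
                     snr = snr, duration = duration),
    MR  = synth_spec("MR", heart_rate = 85, murmur = "systolic",
                     murmur_band = c(80, 250), murmur_level = 0.5,
                     snr = snr, duration = duration),
    MVP = synth_spec("MVP", heart_rate = 75, murmur = "click",
                     murmur_band = c(180, 260), murmur_level = 0.6,
                     snr = snr, duration = duration),
    NHS = synth_spec("NHS", heart_rate = 72, murmur = "none",
                     snr = snr, duration = duration)
  )
}

#' Generate a balanced labelled corpus of synthetic phonocardiograms
#'
#' Draws `n_per_class` records per archetype with per-record jitter of heart
#' rate (±10%), overall amplitude (±20%) and noise realization, mirroring a
#' balanced multi-class corpus. Deterministic given `seed`.
#'
#' @param class_specs Named list of [synth_spec()] objects
#'   (default [default_class_specs()]).
#' @param n_per_class Records per class, or a vector (recycled/named) giving
#'   per-class counts.
#' @param seed Integer seed.
#' @return List with `records` (list of `pcg_record`), `truths` (matching
#'   ground-truth segmentations), `cleans` (pre-noise signals) and `manifest`
#'   (data frame of id, label).
#' @export
synth_corpus <- function(class_specs = default_class_specs(), n_per_class = 20,
                         seed = 1L) {
  counts <- rep_len(n_per_class, length(class_specs))
  if (!is.null(names(n_per_class))) counts <- n_per_class[names(class_specs)]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  records <- list(); truths <- list(); cleans <- list()
  for (ci in seq_along(class_specs)) {
    spec <- class_specs[[ci]]
    for (k in seq_len(counts[ci])) {
      sp <- spec
      sp$heart_rate <- spec$heart_rate * stats::runif(1, 0.9, 1.1)
      amp <- stats::runif(1, 0.8, 1.2)
      rec_seed <- sample.int(.Machine$integer.max, 1)
      g <- synth_pcg(sp, seed = rec_seed)
      g$record$samples <- g$record$samples * amp
      g$record$id <- sprintf("%s_%03d", spec$class_name, k)
      records[[length(records) + 1L]] <- g$record
      truths[[length(truths) + 1L]] <- g$truth
      cleans[[length(cleans) + 1L]] <- g$clean * amp
    }
  }
  manifest <- data.frame(
    id = vapply(records, function(r) r$id, character(1)),
    label = vapply(records, function(r) r$label, character(1)),
    stringsAsFactors = FALSE
  )
  list(records = records, truths = truths, cleans = cleans, manifest = manifest)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
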