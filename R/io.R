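#' @useDynLib pcgfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PIPELINE_FS <- 2205

new_pcg_record <- function(id, samples, fs, label = NA_character_) {
  stopifnot(fs > 0, is.numeric(samples), all(is.finite(samples)))
  structure(list(id = id, samples = as.numeric(samples), fs = fs, label = label),
            class = "pcg_record")
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record '%s': %d samples @ %g Hz, label=%s>\n",
              x$id, length(x$samples), x$fs, x$label))
  invisible(x)
}

# --- minimal RIFF/WAVE PCM support -----------------------------------------
# Reads/writes canonical PCM WAV (16/24/32-bit integer or 32/64-bit float).
# Only the fmt and data chunks are interpreted; other chunks are skipped.

read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id) || length(id) == 0) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (id == "fmt ") {
      body <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(audio_format = u16(0), n_channels = u16(2),
                  sample_rate = u32(4), bits = u16(14))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0) {
    stop("unreadable or empty WAV file: ", path)
  }
  bytes <- fmt$bits / 8
  n_total <- length(data_raw) %/% bytes
  if (fmt$audio_format == 1) {                 # integer PCM
    if (fmt$bits == 24) {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 2^23, v - 2^24, v)
      x <- v / 2^23
    } else {
      v <- readBin(data_raw, "integer", n_total, bytes, signed = TRUE,
                   endian = "little")
      x <- v / 2^(fmt$bits - 1)
    }
  } else if (fmt$audio_format == 3) {          # IEEE float
    x <- readBin(data_raw, "double", n_total, bytes, endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
  }
  if (fmt$n_channels > 1) {                    # average to mono
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  list(samples = x, fs = fmt$sample_rate)
}

#' Write a signal as a 16-bit PCM WAV file
#'
#' @param x Numeric signal; values are scaled so that max |x| maps to full
#'   scale when `normalize = TRUE`, otherwise clipped at ±1.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @param normalize Rescale to full scale before quantization.
#' @export
write_wav <- function(x, fs, path, normalize = TRUE) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  if (normalize && max(abs(x)) > 0) x <- x / max(abs(x))
  v <- as.integer(pmax(pmin(round(x * 32767), 32767), -32768))
  con <- file(path, "wb"); on.exit(close(con))
  data_size <- 2L * length(v)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")         # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(v, con, 2, endian = "little")
  invisible(path)
}

# Rational approximation p/q of a resampling ratio.
ratio_pq <- function(target_fs, fs, max_den = 1000L) {
  r <- target_fs / fs
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err == 0) break
  }
  best
}

#' Load a heart-sound recording
#'
#' Reads a mono (or stereo-averaged) PCM WAV file, resamples it to
#' `target_fs` by polyphase rational resampling with an anti-aliasing
#' low-pass filter, and by default rescales the amplitude so that
#' max |x| = 1. Normalization makes amplitude-scale-dependent features
#' (max, RMS, energy) independent of recording gain; disable it with
#' `normalize = FALSE` if absolute levels matter.
#'
#' @param path WAV file path.
#' @param target_fs Pipeline sampling rate in Hz (default 2205).
#' @param label Optional class label attached to the record.
#' @param normalize Rescale to max |x| = 1 after resampling.
#' @return A `pcg_record`.
#' @export
load_record <- function(path, target_fs = PIPELINE_FS, label = NA_character_,
                        normalize = TRUE) {
  w <- read_wav(path)
  x <- w$samples
  if (!length(x)) stop("empty WAV file: ", path)
  if (max(abs(x)) == 0) stop("degenerate input: zero-amplitude signal in ", path)
  if (w$fs != target_fs) {
    pq <- ratio_pq(target_fs, w$fs)
    x <- as.numeric(signal::resample(x, pq[1], pq[2]))
  }
  if (normalize) x <- x / max(abs(x))
  new_pcg_record(id = sub("\\.[Ww][Aa][Vv]$", "", basename(path)),
                 samples = x, fs = target_fs, label = label)
}

#' Read or write a dataset manifest
#'
#' A manifest is two-column tab-delimited text (`path`, `label`), UTF-8, one
#' recording per row.
#'
#' @param path Manifest file path.
#' @return `read_manifest`: data frame with columns `path`, `label`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("path", "label") %in% names(df))) {
    stop("manifest must have 'path' and 'label' columns")
  }
  if (anyDuplicated(df$path)) stop("manifest paths must be unique")
  df
}

#' @rdname read_manifest
#' @param manifest Data frame with columns `path`, `label`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("path", "label")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write and read feature tables
#'
#' One row per record; columns `id`, `label`, then the 40 (or 36) feature
#' columns in canonical order. Values survive a write/read round trip to at
#' least 12 significant digits.
#'
#' @param features Data frame as produced by [corpus_features()]: columns
#'   `id`, `label`, plus identically-ordered numeric feature columns.
#' @param path CSV file path.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  if (nrow(features)) {
    num <- !(names(features) %in% c("id", "label"))
    if (any(!vapply(features[num], is.numeric, logical(1)))) {
      stop("inconsistent feature table: non-numeric feature columns")
    }
  }
  out <- features
  num <- !(names(out) %in% c("id", "label"))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- !(names(df) %in% c("id", "label"))
  df[num] <- lapply(df[num], as.numeric)
  df
}
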