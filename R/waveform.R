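#' Construct a waveform
#'
#' A waveform is a plain numeric vector of samples carrying its sampling rate
#' as an attribute. All signal-processing functions in modsense consume and
#' return waveforms.
#'
#' @param samples Numeric vector of audio samples.
#' @param sample_rate Sampling rate in Hz.
#' @return A numeric vector of class `"waveform"` with a `sample_rate`
#'   attribute.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' sample_rate(w)
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(as.numeric(samples), sample_rate = as.numeric(sample_rate),
            class = "waveform")
}

#' @rdname waveform
#' @param x A waveform.
#' @export
sample_rate <- function(x) {
  sr <- attr(x, "sample_rate")
  if (is.null(sr)) stop("input has no sample_rate attribute; use waveform()")
  sr
}

#' @exportS3Method base::print
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), rms %.4g>\n",
              length(x), sample_rate(x), length(x) / sample_rate(x), rms(x)))
  invisible(x)
}

# rebuild a waveform with the same rate as a reference
as_waveform_like <- function(samples, ref) waveform(samples, sample_rate(ref))

#' Root-mean-square amplitude
#'
#' @param x Numeric vector.
#' @return RMS value, `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(as.numeric(x)^2))

check_waveform <- function(x, min_len = 2L) {
  if (length(x) < min_len)
    stop("waveform too short: ", length(x), " samples (need >= ", min_len, ")")
  if (!all(is.finite(x))) stop("waveform contains non-finite values")
  invisible(x)
}

#' Derive a child seed deterministically
#'
#' Used throughout the package to fan a single user-facing seed out to
#' independent stochastic sub-operations (clips in a corpus, trials in an
#' experiment, stages of a pipeline) without seed collisions. The map is a
#' fixed affine hash modulo a Mersenne prime, so children stay inside the
#' 32-bit integer range R requires.
#'
#' @param seed Parent integer seed.
#' @param ... One or more integer indices (stage, clip, trial, ...).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Read and write uncompressed WAV files
#'
#' Minimal RIFF/WAVE support: 16-bit PCM and 32-bit IEEE float, mono or the
#' first channel of multichannel files. Covers corpus export/import for the
#' pipeline; it is not a general audio library.
#'
#' @param path File path.
#' @return `wav_read()` returns a [waveform()].
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate     = readBin(con, "integer", 1, 4, endian = "little"),
        byterate = readBin(con, "integer", 1, 4, endian = "little"),
        align    = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path)
  x <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2,
            endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bit)")
  }
  if (fmt$channels > 1L) x <- x[seq(1, length(x), by = fmt$channels)]
  waveform(x, fmt$rate)
}

#' @rdname wav_read
#' @param x A [waveform()] to write.
#' @param bits Either 16 (PCM, clipped to \[-1, 1\]) or 32 (IEEE float).
#' @export
wav_write <- function(x, path, bits = 32L) {
  sr <- as.integer(sample_rate(x))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- as.integer(bits / 8)
  data_sz <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(sr, con, 4, endian = "little")
  writeBin(sr * bytes, con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768)),
             con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}
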