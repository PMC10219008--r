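#' Envelope / temporal-fine-structure decomposition via the analytic signal
#'
#' Computes the Hilbert analytic signal of a real waveform by one-sided
#' spectrum doubling in the FFT domain, and returns its magnitude (the
#' amplitude envelope, Env) and instantaneous phase (the temporal fine
#' structure, TFS). The decomposition is exact in the sense that
#' `Re(env * exp(1i * tfs_phase))` reconstructs the input to numerical
#' precision.
#'
#' @param x A [waveform()] (or numeric vector with a sample rate attribute).
#' @return A list of class `"analytic_decomposition"` with elements `env`
#'   (nonnegative envelope), `tfs_phase` (radians) and `sample_rate`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 1, by = 1 / 4000)), 4000)
#' d <- hilbert_decompose(w)
#' max(abs(Re(d$env * exp(1i * d$tfs_phase)) - w)) < 1e-8
hilbert_decompose <- function(x) {
  check_waveform(x)
  a <- analytic_signal(x)
  structure(list(env = Mod(a), tfs_phase = Arg(a),
                 sample_rate = sample_rate(x)),
            class = "analytic_decomposition")
}

# one-sided analytic signal (complex); x real
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(as.numeric(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Recompose a waveform from an envelope/TFS decomposition
#'
#' @param decomp An `"analytic_decomposition"` from [hilbert_decompose()], or
#'   any list with `env`, `tfs_phase` and `sample_rate`.
#' @return A [waveform()]: `Re(env * exp(1i * tfs_phase))`.
#' @export
recompose <- function(decomp) {
  waveform(Re(decomp$env * exp(1i * decomp$tfs_phase)), decomp$sample_rate)
}

#' Brick-wall FFT bandpass filter
#'
#' Zeroes all FFT bins whose frequency magnitude lies outside `[lo, hi]`
#' (inclusive), the digital-Fourier-transform filtering used for narrowband
#' noise carriers. `lo = 0, hi = nyquist` is the identity.
#'
#' @param x A [waveform()].
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= nyquist`.
#' @return Filtered [waveform()], real-valued.
#' @export
bandpass_fft <- function(x, lo, hi) {
  check_waveform(x)
  nyq <- sample_rate(x) / 2
  if (!(lo >= 0 && lo < hi && hi <= nyq + 1e-9))
    stop("invalid band [", lo, ", ", hi, "] for nyquist ", nyq)
  f <- fft_bin_freqs(length(x), sample_rate(x))
  X <- stats::fft(as.numeric(x))
  X[abs(f) < lo | abs(f) > hi] <- 0
  as_waveform_like(Re(stats::fft(X, inverse = TRUE)) / length(x), x)
}

# signed bin frequencies of an n-point FFT
fft_bin_freqs <- function(n, sr) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * sr / n
}

# keep bins with lo <= |f| < hi (half-open), used by the sub-band partition so
# bands tile the spectrum exactly; include_top closes the last band at nyquist
partition_band <- function(X, f, lo, hi, include_top = FALSE) {
  keep <- abs(f) >= lo & (abs(f) < hi | (include_top & abs(f) <= hi + 1e-9))
  Y <- X
  Y[!keep] <- 0
  Y
}

#' High-pass filter at 20 Hz
#'
#' Brick-wall FFT high-pass used as corpus preprocessing (removes DC and
#' infrasonic drift before training audio is windowed).
#'
#' @param x A [waveform()].
#' @return Filtered [waveform()].
#' @export
highpass20 <- function(x) {
  check_waveform(x)
  f <- fft_bin_freqs(length(x), sample_rate(x))
  X <- stats::fft(as.numeric(x))
  X[abs(f) < 20] <- 0
  as_waveform_like(Re(stats::fft(X, inverse = TRUE)) / length(x), x)
}

#' Apply raised-cosine ramps and scale to a target RMS
#'
#' Applies `ramp_ms` raised-cosine onset/offset ramps, then rescales the
#' whole clip so its RMS equals `target_rms` exactly.
#'
#' @param x A [waveform()].
#' @param ramp_ms Ramp duration in milliseconds (default 10).
#' @param target_rms Target RMS amplitude; `NULL` leaves the level unchanged.
#' @return Ramped, scaled [waveform()].
#' @export
ramp_and_scale <- function(x, ramp_ms = 10, target_rms = NULL) {
  check_waveform(x)
  nr <- round(ramp_ms / 1000 * sample_rate(x))
  if (length(x) <= 2 * nr)
    stop("clip (", length(x), " samples) shorter than two ", ramp_ms, " ms ramps")
  y <- as.numeric(x)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
    y[seq_len(nr)] <- y[seq_len(nr)] * ramp
    y[length(y) - seq_len(nr) + 1] <- y[length(y) - seq_len(nr) + 1] * ramp
  }
  if (!is.null(target_rms)) {
    r <- rms(y)
    if (r == 0) {
      if (target_rms != 0) stop("cannot scale an all-zero clip to a nonzero RMS")
    } else {
      y <- y * (target_rms / r)
    }
  }
  as_waveform_like(y, x)
}

#' ERB-number scale (Glasberg-Moore)
#'
#' `erb_number()` maps frequency in Hz to the ERB-number scale
#' `21.4 * log10(4.37 * f / 1000 + 1)`; `erb_number_inv()` is its inverse.
#' One unit on this scale is one equivalent rectangular bandwidth.
#'
#' @param f Frequency in Hz.
#' @param e ERB number.
#' @return Numeric vector.
#' @export
erb_number <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erb_number
#' @export
erb_number_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Build an ERB-spaced filterbank
#'
#' Center frequencies start at `f_low` and step one ERB on the ERB-number
#' scale until the Nyquist frequency is exceeded. Band edges sit at the
#' ERB-scale midpoints between adjacent centers, with the first edge at 0 Hz
#' and the last at Nyquist, so the bands tile the whole spectrum and
#' sub-band signals sum exactly to the original.
#'
#' @param f_low Lowest center frequency in Hz (default 20).
#' @param nyquist Nyquist frequency in Hz.
#' @return A list of class `"erb_filterbank"`: `center_freqs`, `band_edges`
#'   (length `n_bands + 1`), `n_bands`, `f_low`, `nyquist`.
#' @export
#' @examples
#' build_erb_filterbank(20, 22050)$n_bands  # 42
#' build_erb_filterbank(20, 8000)$n_bands   # 33
build_erb_filterbank <- function(f_low = 20, nyquist) {
  if (!(f_low > 0 && f_low < nyquist)) stop("need 0 < f_low < nyquist")
  e0 <- erb_number(f_low)
  n <- floor(erb_number(nyquist) - e0) + 1
  centers <- erb_number_inv(e0 + seq_len(n) - 1)
  mid <- erb_number_inv((e0 + seq_len(n) - 1)[-n] + 0.5)
  edges <- c(0, mid, nyquist)
  structure(list(center_freqs = centers, band_edges = edges,
                 n_bands = as.integer(n), f_low = f_low, nyquist = nyquist),
            class = "erb_filterbank")
}

#' @exportS3Method base::print
print.erb_filterbank <- function(x, ...) {
  cat(sprintf("<erb_filterbank: %d bands, centers %.1f..%.1f Hz, nyquist %g Hz>\n",
              x$n_bands, x$center_freqs[1], x$center_freqs[x$n_bands], x$nyquist))
  invisible(x)
}

#' Decompose a waveform into ERB-spaced sub-bands
#'
#' Brick-wall FFT partition at the filterbank's band edges. Because each FFT
#' bin belongs to exactly one band, `Reduce("+", subbands)` reproduces the
#' input to numerical precision.
#'
#' @param x A [waveform()].
#' @param bank An `"erb_filterbank"` built for this waveform's Nyquist.
#' @return List of `n_bands` [waveform()]s.
#' @export
subband_decompose <- function(x, bank) {
  check_waveform(x)
  if (abs(bank$nyquist - sample_rate(x) / 2) > 1e-6)
    stop("filterbank nyquist (", bank$nyquist, ") does not match waveform (",
         sample_rate(x) / 2, ")")
  n <- length(x)
  f <- fft_bin_freqs(n, sample_rate(x))
  X <- stats::fft(as.numeric(x))
  lapply(seq_len(bank$n_bands), function(b) {
    Y <- partition_band(X, f, bank$band_edges[b], bank$band_edges[b + 1],
                        include_top = (b == bank$n_bands))
    as_waveform_like(Re(stats::fft(Y, inverse = TRUE)) / n, x)
  })
}

#' Envelope/fine-structure chimera constructions
#'
#' Four degradations of a sound built from its analytic decomposition:
#'
#' * `single_band_env_signal()` keeps the sound's envelope and replaces its
#'   temporal fine structure with that of an equal-RMS white noise:
#'   `Re(Env_x * exp(1i * TFS_wn))`.
#' * `single_band_tfs_signal()` keeps the fine structure and flattens the
#'   envelope to its RMS value: `Re(RMS(Env_x) * exp(1i * TFS_x))`.
#' * `multiband_env_signal()` / `multiband_tfs_signal()` apply the same
#'   construction inside each band of an ERB-spaced filterbank (the noise
#'   fine-structure donor is band-limited to each band) and sum the bands.
#'
#' @param x A [waveform()].
#' @param rng_seed Integer seed for the white-noise fine-structure donor.
#' @param donor Optional waveform supplying the fine structure instead of
#'   fresh white noise (the multiband construction passes the band-matched
#'   noise here).
#' @param bank An `"erb_filterbank"` matching `x`'s Nyquist; built
#'   automatically when `NULL`.
#' @return A [waveform()] of the same length and rate as `x`.
#' @export
single_band_env_signal <- function(x, rng_seed, donor = NULL) {
  check_waveform(x)
  env <- hilbert_decompose(x)$env
  if (is.null(donor)) donor <- white_noise_like(x, rng_seed)
  if (length(donor) != length(x)) stop("donor length must match input")
  tfs_wn <- hilbert_decompose(donor)$tfs_phase
  as_waveform_like(Re(env * exp(1i * tfs_wn)), x)
}

#' @rdname single_band_env_signal
#' @export
single_band_tfs_signal <- function(x) {
  check_waveform(x)
  d <- hilbert_decompose(x)
  flat <- rms(d$env)
  as_waveform_like(Re(flat * exp(1i * d$tfs_phase)), x)
}

#' @rdname single_band_env_signal
#' @export
multiband_env_signal <- function(x, bank = NULL, rng_seed) {
  check_waveform(x)
  if (is.null(bank)) bank <- build_erb_filterbank(20, sample_rate(x) / 2)
  bands <- subband_decompose(x, bank)
  out <- numeric(length(x))
  wn <- white_noise_like(x, rng_seed)
  Xwn <- stats::fft(as.numeric(wn))
  f <- fft_bin_freqs(length(x), sample_rate(x))
  for (b in seq_len(bank$n_bands)) {
    xb <- bands[[b]]
    if (all(xb == 0)) next
    Ywn <- partition_band(Xwn, f, bank$band_edges[b], bank$band_edges[b + 1],
                          include_top = (b == bank$n_bands))
    wnb <- Re(stats::fft(Ywn, inverse = TRUE)) / length(x)
    if (all(wnb == 0)) next
    env_b <- Mod(analytic_signal(xb))
    tfs_b <- Arg(analytic_signal(wnb))
    out <- out + Re(env_b * exp(1i * tfs_b))
  }
  as_waveform_like(out, x)
}

#' @rdname single_band_env_signal
#' @export
multiband_tfs_signal <- function(x, bank = NULL) {
  check_waveform(x)
  if (is.null(bank)) bank <- build_erb_filterbank(20, sample_rate(x) / 2)
  bands <- subband_decompose(x, bank)
  out <- numeric(length(x))
  for (b in seq_len(bank$n_bands)) {
    xb <- bands[[b]]
    if (all(xb == 0)) next
    a <- analytic_signal(xb)
    flat <- rms(Mod(a))
    out <- out + Re(flat * exp(1i * Arg(a)))
  }
  as_waveform_like(out, x)
}

# gaussian white noise with the same length/rate and RMS as x
white_noise_like <- function(x, rng_seed) {
  wn <- with_seed(rng_seed, stats::rnorm(length(x)))
  r <- rms(x)
  if (r > 0) wn <- wn * (r / rms(wn))
  as_waveform_like(wn, x)
}

#' Modulation (envelope) spectrum of a waveform
#'
#' Hilbert envelope, mean removed, one-sided FFT magnitude: a quick look at
#' which modulation rates dominate a sound. Used by tests and by the
#' synthetic-corpus separability oracle.
#'
#' @param x A [waveform()].
#' @return A tibble with `rate_hz` and `magnitude`.
#' @export
envelope_spectrum <- function(x) {
  check_waveform(x)
  env <- hilbert_decompose(x)$env
  env <- env - mean(env)
  n <- length(env)
  mag <- Mod(stats::fft(env))[seq_len(floor(n / 2))]
  tibble::tibble(rate_hz = (seq_len(floor(n / 2)) - 1) * sample_rate(x) / n,
                 magnitude = mag)
}
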