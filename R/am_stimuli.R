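#' Apply sinusoidal amplitude modulation to a carrier
#'
#' Multiplies a carrier by `1 + a * sin(2 * pi * f * t + phase)` where the
#' linear modulation index is `a = 10^(depth_db / 20)`. Depth 0 dB is full
#' modulation (`a = 1`, envelope minima reach 0); `-Inf` dB leaves the
#' carrier unmodulated; positive depths are over-modulation and rejected.
#'
#' @param carrier A [waveform()].
#' @param rate_hz AM rate in Hz, below the Nyquist frequency.
#' @param depth_db AM depth in dB (`<= 0`; `-Inf` allowed).
#' @param phase AM starting phase in radians (default 0).
#' @return Modulated [waveform()].
#' @export
#' @examples
#' c0 <- waveform(rep(1, 8000), 8000)
#' range(apply_am(c0, 4, 0))  # ~0 .. ~2
apply_am <- function(carrier, rate_hz, depth_db, phase = 0) {
  check_waveform(carrier)
  if (depth_db > 0) stop("over-modulation: depth_db must be <= 0, got ", depth_db)
  if (rate_hz <= 0 || rate_hz >= sample_rate(carrier) / 2)
    stop("AM rate must be in (0, nyquist)")
  a <- 10^(depth_db / 20)  # 0 when depth_db = -Inf
  t <- (seq_along(carrier) - 1) / sample_rate(carrier)
  as_waveform_like(as.numeric(carrier) * (1 + a * sin(2 * pi * rate_hz * t + phase)),
                   carrier)
}

#' The six psychophysical AM-detection stimulus conditions
#'
#' One row per condition of the simulated human experiments. Conditions are
#' named by carrier bandwidth (`nb2`, `nb3`, `nb31`, `nb314` for 2/3/31/314 Hz
#' narrowband carriers; `bb_short`, `bb_long` for broadband carriers of 0.5 s
#' and 2 s). Columns encode the per-study procedure: stimulus duration, AM
#' starting phase (fixed at zero or drawn per stimulus), whether RMS
#' equalization happens before or after modulation, whether the carrier
#' band-limiting happens before or after modulation, the number of
#' forced-choice intervals, and the tested depth grid (`-60..0` dB for the
#' 2 Hz-bandwidth condition, `-40..0` dB otherwise, in 4 dB steps).
#'
#' AM-rate ranges and the narrowband center frequency are not condition
#' constants of the original experiments that this package can restate; the
#' defaults span the ranges typical of the source studies and are plain
#' columns a caller can overwrite.
#'
#' @param sample_rate_hz Sampling rate used to realize stimuli (default 44100).
#' @param center_freq_hz Narrowband carrier center frequency (default 5000).
#' @param target_rms Stimulus RMS (default 1; amplitude is in arbitrary
#'   units, and stimuli should share the training corpus RMS).
#' @return A tibble with one row per condition.
#' @export
am_conditions <- function(sample_rate_hz = 44100, center_freq_hz = 5000,
                          target_rms = 1) {
  cond <- tibble::tribble(
    ~condition, ~carrier_bandwidth_hz, ~duration_s, ~phase_mode, ~equalize_order,
    ~bandpass_order, ~n_intervals, ~rate_lo_hz, ~rate_hi_hz, ~depth_lo_db,
    "nb2",      2,    2,   "random", "after",  "before", 2L, 2,  64,  -60,
    "nb3",      3,    1,   "fixed",  "after",  "before", 3L, 3, 100,  -40,
    "nb31",     31,   1,   "fixed",  "after",  "before", 3L, 3, 100,  -40,
    "nb314",    314,  1,   "fixed",  "after",  "after",  3L, 3, 800,  -40,
    "bb_short", Inf,  0.5, "fixed",  "before", "none",   2L, 4, 256,  -40,
    "bb_long",  Inf,  2,   "random", "after",  "none",   2L, 2, 1024, -40)
  cond$depth_hi_db <- 0
  cond$depth_step_db <- 4
  cond$n_rates <- 8L
  cond$center_freq_hz <- ifelse(is.finite(cond$carrier_bandwidth_hz),
                                center_freq_hz, NA_real_)
  cond$sample_rate_hz <- sample_rate_hz
  cond$target_rms <- target_rms
  cond
}

# coerce a one-row condition tibble (or list) to a named list
as_condition <- function(cond) {
  if (is.data.frame(cond)) {
    stopifnot(nrow(cond) == 1L)
    cond <- as.list(cond)
  }
  cond
}

#' AM rates of a condition
#'
#' Eight (by default) rates evenly spaced on a log scale across the
#' condition's rate range.
#'
#' @param cond One row of [am_conditions()].
#' @return Numeric vector of AM rates in Hz.
#' @export
condition_rates <- function(cond) {
  cond <- as_condition(cond)
  exp(seq(log(cond$rate_lo_hz), log(cond$rate_hi_hz), length.out = cond$n_rates))
}

#' Depth grid of a condition
#'
#' @param cond One row of [am_conditions()].
#' @return Depths in dB from `depth_lo_db` to `depth_hi_db` in
#'   `depth_step_db` steps.
#' @export
condition_depths <- function(cond) {
  cond <- as_condition(cond)
  seq(cond$depth_lo_db, cond$depth_hi_db, by = cond$depth_step_db)
}

#' Generate one psychophysical stimulus
#'
#' Realizes a (possibly unmodulated) stimulus under a condition's procedure:
#' a fresh Gaussian noise carrier per call, band-limited before or after
#' modulation as the condition dictates, RMS-equalized before or after
#' modulation, with the AM starting phase fixed at zero or drawn uniformly,
#' and 10 ms raised-cosine ramps. When equalization is `"after"` the final
#' RMS equals `target_rms` exactly; when `"before"` the carrier is set to
#' `target_rms` and modulation is applied on top (so the final level varies
#' with depth as `1 + a^2/2` in power).
#'
#' @param cond One row of [am_conditions()].
#' @param rate_hz AM rate in Hz.
#' @param depth_db AM depth in dB.
#' @param modulated Logical; `FALSE` produces the unmodulated interval.
#' @param rng_seed Integer seed; a fixed seed gives a byte-identical stimulus.
#' @return A [waveform()].
#' @export
make_stimulus <- function(cond, rate_hz, depth_db, modulated = TRUE, rng_seed) {
  cond <- as_condition(cond)
  sr <- cond$sample_rate_hz
  if (rate_hz <= 0 || rate_hz >= sr / 2) stop("AM rate outside (0, nyquist)")
  n <- round(cond$duration_s * sr)
  with_seed(rng_seed, {
    x <- waveform(stats::rnorm(n), sr)
    narrow <- is.finite(cond$carrier_bandwidth_hz)
    band <- if (narrow) {
      c(max(0, cond$center_freq_hz - cond$carrier_bandwidth_hz / 2),
        cond$center_freq_hz + cond$carrier_bandwidth_hz / 2)
    }
    if (narrow && cond$bandpass_order == "before") {
      x <- bandpass_fft(x, band[1], band[2])
    }
    if (cond$equalize_order == "before") {
      x <- as_waveform_like(as.numeric(x) * cond$target_rms / rms(x), x)
    }
    if (modulated) {
      phase <- if (identical(cond$phase_mode, "random")) {
        stats::runif(1, 0, 2 * pi)
      } else 0
      x <- apply_am(x, rate_hz, depth_db, phase)
    }
    if (narrow && cond$bandpass_order == "after") {
      x <- bandpass_fft(x, band[1], band[2])
    }
    if (cond$equalize_order == "after") {
      ramp_and_scale(x, 10, cond$target_rms)
    } else {
      ramp_and_scale(x, 10, NULL)
    }
  })
}

#' Probe stimuli for simulated neurophysiology
#'
#' Fully modulated (0 dB depth) broadband white-noise stimuli at each
#' requested AM rate, with independent carriers per repeat. These are the
#' inputs from which unit AM tuning curves are measured.
#'
#' @param rates_hz AM rates in Hz.
#' @param sample_rate_hz Sampling rate.
#' @param duration_s Stimulus duration in seconds.
#' @param n_repeats Independent carrier instances per rate.
#' @param rng_seed Integer seed.
#' @param target_rms Stimulus RMS (default 1).
#' @return A tibble with columns `rate_hz`, `repeat_idx` and a `wave`
#'   list-column of [waveform()]s.
#' @export
neurophys_probe_set <- function(rates_hz, sample_rate_hz, duration_s,
                                n_repeats = 10, rng_seed, target_rms = 1) {
  if (length(rates_hz) == 0) {
    return(tibble::tibble(rate_hz = numeric(), repeat_idx = integer(),
                          wave = list()))
  }
  if (any(rates_hz <= 0) || any(rates_hz >= sample_rate_hz / 2))
    stop("probe rates must lie in (0, nyquist)")
  grid <- tidyr::expand_grid(rate_hz = rates_hz,
                             repeat_idx = seq_len(n_repeats))
  n <- round(duration_s * sample_rate_hz)
  grid$wave <- purrr::pmap(grid, function(rate_hz, repeat_idx) {
    with_seed(derive_seed(rng_seed, match(rate_hz, rates_hz), repeat_idx), {
      x <- waveform(stats::rnorm(n), sample_rate_hz)
      x <- apply_am(x, rate_hz, 0)
      ramp_and_scale(x, 10, target_rms)
    })
  })
  grid
}
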