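#' Specify a synthetic sound corpus
#'
#' Defines a labeled corpus whose categories are discriminable through their
#' amplitude-modulation statistics and carrier spectra, standing in for
#' natural-sound datasets. Each category has a modulation spectrum
#' concentrated in a Gaussian bump on the log-rate axis (center, log
#' bandwidth, depth) and a carrier spectral tilt in dB/octave; each clip
#' draws a fresh modulator and carrier from its category's distribution, so
#' classification is non-trivial within categories.
#'
#' Defaults are the corpus conditions used throughout the package's own
#' experiments: 10 categories x 40 clips of 1 s at 16 kHz, modulation
#' centers log-spaced 4-128 Hz, tilts spread over -6..+6 dB/octave, a -40 dB
#' noise floor, and 0.6/0.2/0.2 update/early-stop/validation splits.
#'
#' @param n_categories Number of categories.
#' @param clips_per_category Clips per category.
#' @param sample_rate_hz Sampling rate.
#' @param clip_duration_s Clip duration in seconds (must fit at least two
#'   cycles of the slowest category modulation center).
#' @param mod_center_hz Per-category modulation centers; default log-spaced
#'   4-128 Hz.
#' @param mod_log_bandwidth_oct Gaussian bump standard deviation in octaves.
#' @param mod_depth Modulation depth of the category modulator (0-1).
#' @param carrier_tilt_db_oct Per-category carrier spectral tilts; default
#'   spread over -6..+6 dB/octave.
#' @param noise_floor_db Additive noise floor relative to clip RMS.
#' @param target_rms Clip RMS after preprocessing.
#' @param split_fractions Named fractions for `update`, `earlystop`,
#'   `validation`; must sum to 1.
#' @param rng_seed Integer seed.
#' @return A list of class `"corpus_spec"`.
#' @export
synthetic_corpus_spec <- function(n_categories = 10, clips_per_category = 40,
                                  sample_rate_hz = 16000, clip_duration_s = 1,
                                  mod_center_hz = NULL,
                                  mod_log_bandwidth_oct = 0.5,
                                  mod_depth = 0.8,
                                  carrier_tilt_db_oct = NULL,
                                  noise_floor_db = -40, target_rms = 1,
                                  split_fractions = c(update = 0.6,
                                                      earlystop = 0.2,
                                                      validation = 0.2),
                                  rng_seed = 1) {
  if (is.null(mod_center_hz))
    mod_center_hz <- 2^seq(2, 7, length.out = n_categories)
  if (is.null(carrier_tilt_db_oct))
    carrier_tilt_db_oct <- seq(-6, 6, length.out = n_categories)
  if (length(mod_center_hz) != n_categories ||
      length(carrier_tilt_db_oct) != n_categories)
    stop("per-category parameter vectors must have length n_categories")
  if (anyDuplicated(paste(mod_center_hz, carrier_tilt_db_oct)))
    stop("category parameter sets must be pairwise distinct")
  if (abs(sum(split_fractions) - 1) > 1e-9 ||
      !all(c("update", "earlystop", "validation") %in% names(split_fractions)))
    stop("split_fractions must name update/earlystop/validation and sum to 1")
  if (clip_duration_s < 2 / min(mod_center_hz))
    stop("clip too short: needs >= 2 cycles of the slowest modulation center (",
         min(mod_center_hz), " Hz)")
  structure(list(n_categories = as.integer(n_categories),
                 clips_per_category = as.integer(clips_per_category),
                 sample_rate_hz = sample_rate_hz,
                 clip_duration_s = clip_duration_s,
                 mod_center_hz = mod_center_hz,
                 mod_log_bandwidth_oct = mod_log_bandwidth_oct,
                 mod_depth = mod_depth,
                 carrier_tilt_db_oct = carrier_tilt_db_oct,
                 noise_floor_db = noise_floor_db, target_rms = target_rms,
                 split_fractions = split_fractions,
                 rng_seed = as.integer(rng_seed)),
            class = "corpus_spec")
}

# one clip: tilted-noise carrier amplitude-modulated by a narrowband
# (on the log-rate axis) noise modulator, plus a noise floor
synth_clip <- function(spec, cat_idx, clip_seed) {
  sr <- spec$sample_rate_hz
  n <- round(spec$clip_duration_s * sr)
  with_seed(clip_seed, {
    f <- abs(fft_bin_freqs(n, sr))
    # carrier: white noise spectrally tilted around 1 kHz
    carrier <- stats::rnorm(n)
    gain <- ifelse(f > 0, 10^(spec$carrier_tilt_db_oct[cat_idx] *
                                log2(pmax(f, sr / n) / 1000) / 20), 0)
    carrier <- Re(stats::fft(stats::fft(carrier) * gain, inverse = TRUE)) / n
    carrier <- carrier / rms(carrier)
    # modulator: unit-variance noise band-limited to a log-rate bump
    z <- stats::rnorm(n)
    w <- ifelse(f > 0,
                exp(-(log2(pmax(f, 1e-6) / spec$mod_center_hz[cat_idx]))^2 /
                      (2 * spec$mod_log_bandwidth_oct^2)), 0)
    z <- Re(stats::fft(stats::fft(z) * w, inverse = TRUE)) / n
    z <- z / stats::sd(z)
    modulator <- pmax(1 + spec$mod_depth * z, 0)
    y <- carrier * modulator
    y <- y + stats::rnorm(n) * rms(y) * 10^(spec$noise_floor_db / 20)
    x <- waveform(y, sr)
    ramp_and_scale(highpass20(x), 10, spec$target_rms)
  })
}

#' Generate a labeled synthetic corpus
#'
#' Deterministic for a fixed spec seed (clip seeds are derived per clip
#' index). Splits are assigned within each category by the spec's fractions.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @return A corpus tibble: `clip_id`, `category`, `split`, `seed`, and a
#'   `wave` list-column of [waveform()]s; the spec is attached as an
#'   attribute.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  ncl <- spec$clips_per_category
  n_upd <- round(spec$split_fractions["update"] * ncl)
  n_es <- round(spec$split_fractions["earlystop"] * ncl)
  split_vec <- c(rep("update", n_upd), rep("earlystop", n_es),
                 rep("validation", ncl - n_upd - n_es))
  rows <- tidyr::expand_grid(cat_idx = seq_len(spec$n_categories),
                             clip_idx = seq_len(ncl))
  out <- rows |>
    dplyr::mutate(
      clip_id = sprintf("cat%02d_clip%03d", .data$cat_idx, .data$clip_idx),
      category = sprintf("cat%02d", .data$cat_idx),
      split = split_vec[.data$clip_idx],
      seed = purrr::map2_int(.data$cat_idx, .data$clip_idx,
                             ~derive_seed(spec$rng_seed, .x, .y)))
  out$wave <- purrr::pmap(out[c("cat_idx", "seed")], function(cat_idx, seed)
    synth_clip(spec, cat_idx, seed))
  out <- dplyr::select(out, "clip_id", "category", "split", "seed", "wave")
  attr(out, "spec") <- spec
  out
}

#' Degrade a corpus with envelope/fine-structure chimeras
#'
#' Maps each clip through one of the four chimera constructions: `env1` /
#' `tfs1` (single band) or `envN` / `tfsN` (per-band over an ERB-spaced
#' filterbank built for the corpus Nyquist). Only training audio should be
#' degraded; AM-detection stimuli never are. The manifest is preserved; a
#' `mode` column records the degradation.
#'
#' @param corpus A corpus tibble from [generate_corpus()] (any tibble with a
#'   `wave` list-column and `seed` column works).
#' @param mode One of `"env1"`, `"envN"`, `"tfs1"`, `"tfsN"`.
#' @param rng_seed Seed for the noise fine-structure donors (env modes).
#' @return The corpus tibble with transformed audio and a `mode` column.
#' @export
degraded_corpus <- function(corpus, mode = c("env1", "envN", "tfs1", "tfsN"),
                            rng_seed = 1) {
  mode <- match.arg(mode)
  sr <- sample_rate(corpus$wave[[1]])
  bank <- if (mode %in% c("envN", "tfsN")) build_erb_filterbank(20, sr / 2)
  out <- corpus
  out$wave <- purrr::imap(corpus$wave, function(w, i) {
    sd <- derive_seed(rng_seed, 101L, i)
    switch(mode,
           env1 = single_band_env_signal(w, sd),
           tfs1 = single_band_tfs_signal(w),
           envN = multiband_env_signal(w, bank, sd),
           tfsN = multiband_tfs_signal(w, bank))
  })
  out$mode <- mode
  attr(out, "spec") <- attr(corpus, "spec")
  out
}

#' Envelope-spectrum centroid of a clip
#'
#' The power-weighted mean log2 modulation rate over `rate_range`; a
#' one-number summary of where a clip's modulation energy sits, used as the
#' independent separability oracle for synthetic corpora. Power weighting
#' keeps the broadband envelope noise floor from dominating the centroid.
#'
#' @param x A [waveform()].
#' @param rate_range Modulation-rate band over which to compute the
#'   centroid (Hz).
#' @return Centroid in log2(Hz).
#' @export
envelope_centroid <- function(x, rate_range = c(1, 256)) {
  es <- envelope_spectrum(x)
  es <- es[es$rate_hz >= rate_range[1] & es$rate_hz <= rate_range[2], ]
  sum(log2(es$rate_hz) * es$magnitude^2) / sum(es$magnitude^2)
}

#' Write a corpus to WAV files with a manifest
#'
#' @param corpus A corpus tibble.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble (with `path` column), invisibly; also written
#'   as `manifest.csv` in `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(corpus$clip_id, ".wav"))
  purrr::walk2(corpus$wave, paths, wav_write)
  manifest <- dplyr::mutate(
    dplyr::select(corpus, -"wave"), path = basename(paths))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory containing `manifest.csv` and WAV files.
#' @return A corpus tibble.
#' @export
read_corpus <- function(dir) {
  manifest <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE))
  manifest$wave <- purrr::map(file.path(dir, manifest$path), wav_read)
  manifest
}
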