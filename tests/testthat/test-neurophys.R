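test_that("vector strength matches its definition on known traces", {
  sr <- 1000
  t <- (0:999) / sr
  # constant trace: no modulation energy, synchrony 0
  expect_equal(vector_strength(rep(2, 1000), 8, sr), 0)
  # a (nonnegative) raised sinusoid at f: high synchrony at f
  a <- 1 + sin(2 * pi * 8 * t)
  expect_gt(vector_strength(a, 8, sr), 0.45)  # VS of 1+sin is 0.5
  expect_equal(vector_strength(a, 8, sr), 0.5, tolerance = 1e-3)
  expect_lt(vector_strength(a, 13, sr), 0.05)
})

test_that("envelope-tracking units show synchrony; constants do not", {
  sr <- 8000
  # observer whose unit 1 is the stimulus envelope, unit 2 a constant
  obs <- function(wave) rbind(hilbert_decompose(wave)$env, rep(1, length(wave)))
  tu <- measure_tuning(obs, rates_hz = c(8, 32, 128), sample_rate_hz = sr,
                       duration_s = 0.25, n_repeats = 2, rng_seed = 4)
  sync1 <- tu$sync_tuning[tu$unit == 1]
  sync2 <- tu$sync_tuning[tu$unit == 2]
  expect_true(all(sync1 > 0.3))  # envelope locks to the modulator
  expect_true(all(sync2 == 0))   # constant output has zero synchrony
  # rate above the activity Nyquist is excluded with a flag
  tu2 <- measure_tuning(obs, rates_hz = c(8, sr), sample_rate_hz = sr,
                        duration_s = 0.25, n_repeats = 1, rng_seed = 4)
  expect_equal(attr(tu2, "excluded_rates"), sr)
  # reproducible bit for bit under a fixed seed
  tu3 <- measure_tuning(obs, rates_hz = c(8, 32, 128), sample_rate_hz = sr,
                        duration_s = 0.25, n_repeats = 2, rng_seed = 4)
  expect_identical(tu$sync_tuning, tu3$sync_tuning)
})

test_that("a bandpass-modulation unit recovers its center as best rate", {
  sr <- 8000
  make_bp_observer <- function(center_hz) {
    function(wave) {
      e <- waveform(hilbert_decompose(wave)$env, sample_rate(wave))
      e <- waveform(as.numeric(e) - mean(e), sr)
      bp <- bandpass_fft(e, center_hz / 1.4, center_hz * 1.4)
      matrix(as.numeric(bp)^2, nrow = 1)
    }
  }
  rates <- 2^(2:8)  # 4..256 Hz
  tu <- measure_tuning(make_bp_observer(32), rates_hz = rates,
                       sample_rate_hz = sr, duration_s = 0.5, n_repeats = 3,
                       rng_seed = 11)
  ch <- tuning_characteristics(tu)
  best_rate_coded <- ch$best_rate[ch$coding == "rate"]
  expect_equal(best_rate_coded, 32)
})

test_that("best/cutoff extraction follows argmax and -3 dB interpolation", {
  rates <- c(8, 16, 32, 64, 128)
  # monotone decreasing: best at the lowest rate
  bc <- best_and_cutoff(c(5, 4, 3, 2, 1), rates)
  expect_equal(bc$best_rate, 8)
  # triangular curve: hand-computed log-interpolated cutoff
  v <- c(0, 0.5, 1, 0.5, 0)
  bc2 <- best_and_cutoff(v, rates)
  expect_equal(bc2$best_rate, 32)
  frac <- (1 - 0.707) / (1 - 0.5)
  expect_equal(bc2$upper_cutoff, 2^(log2(32) + frac * 1), tolerance = 1e-9)
  expect_gte(bc2$upper_cutoff, bc2$best_rate)
  # ties go to the lowest rate
  expect_equal(best_and_cutoff(c(1, 5, 5, 1, 0), rates)$best_rate, 16)
  # flat curve: invalid, excluded
  expect_false(best_and_cutoff(rep(2, 5), rates)$valid)
  expect_false(best_and_cutoff(rep(0, 5), rates)$valid)
})

test_that("ks similarity matches ECDF enumeration and rank invariance", {
  expect_equal(ks_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(ks_similarity(1:3, 11:13), 0.0)
  # enumerated toy case: sup difference is 1/3 at the value 3
  expect_equal(ks_similarity(c(1, 2, 3), c(1, 2, 4)), 1 - 1 / 3)
  # cross-check against the stats::ks.test statistic
  set.seed(31)
  a <- rlnorm(40, 3, 1); b <- rlnorm(25, 3.5, 0.8)
  D <- suppressWarnings(stats::ks.test(a, b)$statistic)
  expect_equal(ks_similarity(a, b), 1 - unname(D), tolerance = 1e-12)
  # symmetric, bounded, invariant to monotone transforms of both samples
  expect_equal(ks_similarity(a, b), ks_similarity(b, a))
  expect_gte(ks_similarity(a, b), 0); expect_lte(ks_similarity(a, b), 1)
  expect_equal(ks_similarity(a, b), ks_similarity(a^2, b^2), tolerance = 1e-12)
  expect_error(ks_similarity(numeric(0), 1), "nonempty")
})

test_that("layer-region mapping ranks matching distributions first", {
  # toy: 3 hand-made units whose characteristics equal region A's sample
  chars <- tibble::tibble(
    layer = 1, coding = "rate",
    best_rate = c(10, 20, 40), upper_cutoff = c(20, 40, 80), valid = TRUE)
  refA <- tibble::tibble(region = "A", characteristic = "rate_best",
                         rate_hz = c(10, 20, 40)) |>
    dplyr::bind_rows(tibble::tibble(region = "A",
                                    characteristic = "rate_cutoff",
                                    rate_hz = c(20, 40, 80)))
  refB <- tibble::tibble(region = "B", characteristic = "rate_best",
                         rate_hz = c(1000, 2000, 4000)) |>
    dplyr::bind_rows(tibble::tibble(region = "B",
                                    characteristic = "rate_cutoff",
                                    rate_hz = c(2000, 4000, 8000)))
  sim <- layer_region_map(chars, dplyr::bind_rows(refA, refB))
  expect_equal(sim$similarity[sim$region == "A"], 1.0)
  expect_equal(sim$similarity[sim$region == "B"], 0.0)
  # hand-enumerated ECDF arithmetic on a 2-region toy
  refC <- tibble::tibble(region = "C", characteristic = "rate_best",
                         rate_hz = c(10, 20, 80))
  simC <- layer_region_map(chars, refC)
  expect_equal(simC$similarity, 1 - 1 / 3)
  # all-invalid layer is an error
  expect_error(layer_region_map(dplyr::mutate(chars, valid = FALSE), refA),
               "no valid")
})

test_that("an envelope-filter layer drawn from a region ranks that region first", {
  sr <- 8000
  ref <- synthetic_region_reference(n_per_region = 30, rng_seed = 77)
  # build a fake layer whose units are bandpass modulation filters with
  # centers drawn from the IC sync-best fixture distribution
  ic_centers <- ref$rate_hz[ref$region == "IC" &
                              ref$characteristic == "sync_best"]
  ic_centers <- pmin(pmax(ic_centers, 4), 400)[1:20]
  obs <- function(wave) {
    e <- as.numeric(hilbert_decompose(wave)$env)
    e <- e - mean(e)
    do.call(rbind, lapply(ic_centers, function(fc) {
      as.numeric(bandpass_fft(waveform(e, sr), fc / 1.4, fc * 1.4)) + 1
    }))
  }
  rates <- 2^seq(1, 9, length.out = 12)
  tu <- measure_tuning(obs, rates_hz = rates, sample_rate_hz = sr,
                       duration_s = 0.5, n_repeats = 2, rng_seed = 13)
  ch <- dplyr::mutate(tuning_characteristics(tu), layer = 1)
  sim <- layer_region_map(ch, ref[ref$characteristic == "sync_best", ])
  best_region <- sim$region[which.max(sim$similarity)]
  expect_identical(best_region, "IC")
})
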