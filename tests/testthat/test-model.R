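test_that("receptive field follows the dilation formula", {
  expect_identical(receptive_field(list(filter_sizes = c(1, 1, 1),
                                        dilations = c(5, 9, 2))), 1L)
  expect_identical(receptive_field(list(filter_sizes = 3, dilations = 10)), 21L)
  # the four published architectures all fit the 0.2 s window at 44.1 kHz,
  # oracle: per-layer sum of (filter - 1) * dilation
  for (arch in table1_architectures()) {
    oracle <- 1 + sum((arch$filter_sizes - 1) * arch$dilations)
    expect_identical(receptive_field(arch), as.integer(oracle))
    expect_lte(oracle, 8820)
  }
  expect_error(receptive_field(list(filter_sizes = c(0, 2),
                                    dilations = c(1, 1))), "positive")
})

test_that("sampled architectures always respect the window constraint", {
  ok <- vapply(1:200, function(i) {
    L <- sample(c(7, 9, 11, 13), 1)
    a <- sample_architecture(L, 8820, rng_seed = i)
    receptive_field(a) <= 8820 &&
      all(a$filter_sizes >= 2 & a$filter_sizes <= 8) &&
      a$units %in% c(32, 64, 128, 256, 512)
  }, logical(1))
  expect_true(all(ok))
  a1 <- sample_architecture(13, 8820, rng_seed = 7)
  a2 <- sample_architecture(13, 8820, rng_seed = 7)
  expect_identical(a1, a2)
  expect_error(sample_architecture(7, 5, rng_seed = 1), "unsatisfiable")
})

test_that("forward pass matches the convolution/ELU definitions", {
  arch <- architecture(2, 4, c(3, 2), c(5, 7), 3, 50)
  m <- init_model(arch, 11)
  # zero weights and biases: zero activations, uniform softmax
  m0 <- m
  m0$W <- lapply(m0$W, function(lw) lapply(lw, function(w) w * 0))
  m0$V <- m0$V * 0
  set.seed(1)
  x <- waveform(rnorm(100), 1000)
  out <- forward(m0, x, record_layers = 1:2)
  expect_true(all(out$activations[["1"]] == 0))
  expect_true(all(out$activations[["2"]] == 0))
  p <- exp(out$logits[, 1]) / sum(exp(out$logits[, 1]))
  expect_equal(p, rep(1 / 3, 3))
  # ELU definition: negative preactivations map to exp(z) - 1
  expect_equal(modsense:::elu(c(-1, 0.5, 0)), c(expm1(-1), 0.5, 0))
  # translation equivariance: shifting the input shifts interior activations
  shift <- 3
  x2 <- waveform(c(as.numeric(x)[(shift + 1):100], rnorm(shift)), 1000)
  a1 <- layer_activations(m, x, 2)
  a2 <- layer_activations(m, x2, 2)
  keep <- 1:(ncol(a2) - shift)
  expect_equal(a2[, keep], a1[, keep + shift], tolerance = 1e-10)
  expect_error(forward(m, waveform(rnorm(10), 1000)), "receptive field")
})

test_that("recognition evaluation time-averages the classification output", {
  arch <- architecture(1, 2, 1, 1, 2, 10)
  m <- init_model(arch, 1, categories = c("a", "b"))
  # rig the network so category scores follow the input sign directly
  m$W[[1]][[1]] <- matrix(c(5, -5), 2, 1)
  m$b[[1]] <- c(0, 0)
  m$V <- diag(2)
  m$c <- c(0, 0)
  corpus <- tibble::tibble(
    wave = list(waveform(rep(1, 40), 100), waveform(rep(-1, 40), 100)),
    category = c("a", "b"))
  expect_equal(evaluate_recognition(m, corpus), 1.0)
  corpus_bad <- dplyr::mutate(corpus, category = rev(category))
  expect_equal(evaluate_recognition(m, corpus_bad), 0.0)
  # span evaluation degenerates to per-frame argmax on a single-frame span
  corpus_sp <- dplyr::mutate(
    corpus, spans = list(data.frame(start = 20, end = 20, category = "a"),
                         data.frame(start = 20, end = 20, category = "b")))
  expect_equal(evaluate_recognition(m, corpus_sp, use_spans = TRUE), 1.0)
  expect_error(evaluate_recognition(
    m, dplyr::mutate(corpus, spans = list(
      data.frame(start = 1, end = 99, category = "a"),
      data.frame(start = 1, end = 10, category = "b"))),
    use_spans = TRUE), "span outside clip")
})

test_that("untrained models sit at chance on a balanced corpus", {
  spec <- toy_corpus_spec(clips_per_category = 8)
  corpus <- generate_corpus(spec)
  m <- init_model(tiny_arch(), 5)
  m$categories <- sort(unique(corpus$category))
  acc <- evaluate_recognition(m, corpus)
  expect_gte(acc, 0); expect_lte(acc, 1)
  # chance is 1/3; an untrained model can deviate but not be near-perfect
  expect_lt(acc, 0.8)
})

test_that("early stopping obeys its patience contract", {
  spec <- toy_corpus_spec(clips_per_category = 5, rng_seed = 3)
  corpus <- generate_corpus(spec)
  m <- init_model(tiny_arch(), 5)
  # zero learning rate freezes the loss: patience 1 stops after epoch 2
  # (epoch 1 improves on -Inf, epoch 2 does not improve)
  cfg <- training_config(learning_rate = 1e-30, patience_epochs = 1,
                         max_epochs = 50, rng_seed = 2)
  m2 <- train_model(m, corpus, cfg)
  expect_identical(nrow(m2$training_log), 2L)
  expect_true(m2$frozen)
  expect_error(train_model(m, corpus[corpus$split == "update", ], cfg),
               "splits")
})

test_that("checkpoints round-trip through JSON", {
  arch <- architecture(2, 3, c(2, 3), c(4, 5), 2, 30)
  m <- init_model(arch, 9, categories = c("x", "y"))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$arch, m$arch)
  expect_identical(m2$categories, m$categories)
  set.seed(4)
  x <- waveform(rnorm(60), 500)
  expect_equal(forward(m, x)$logits, forward(m2, x)$logits, tolerance = 1e-12)
  unlink(path)
})

test_that("a controlled two-group search selects the better layer count", {
  # toy corpus and tiny budgets; the 'search' contract under test is the
  # group ranking by mean of the best-k accuracies and the survivor retrain
  spec <- toy_corpus_spec(clips_per_category = 6, rng_seed = 17)
  corpus <- generate_corpus(spec)
  res <- architecture_search(
    corpus, layer_counts = c(1, 2), n_candidates = 2, best_k = 2,
    patience1 = 1, patience2 = 1,
    config = training_config(learning_rate = 1e-4, max_epochs = 2,
                             batch_size = 8),
    rng_seed = 5, input_window_samples = 800,
    units_choices = 8, filter_range = c(2, 4))
  expect_identical(length(res$models), 2L)
  expect_true(all(vapply(res$models, function(m) isTRUE(m$frozen), logical(1))))
  expect_identical(nrow(res$step1), 4L)
  expect_true(res$selected_layers %in% c(1, 2))
  # deterministic given the seed
  res2 <- architecture_search(
    corpus, layer_counts = c(1, 2), n_candidates = 2, best_k = 2,
    patience1 = 1, patience2 = 1,
    config = training_config(learning_rate = 1e-4, max_epochs = 2,
                             batch_size = 8),
    rng_seed = 5, input_window_samples = 800,
    units_choices = 8, filter_range = c(2, 4))
  expect_identical(res$selected_layers, res2$selected_layers)
  expect_identical(model_checksum(res$models[[1]]),
                   model_checksum(res2$models[[1]]))
  expect_error(architecture_search(corpus, layer_counts = 1, n_candidates = 1,
                                   best_k = 2, input_window_samples = 800),
               "best_k")
})
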