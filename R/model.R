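#' Define a layered dilated-convolution architecture
#'
#' Each layer is a one-dimensional convolution along time with its own filter
#' size and dilation width, followed by an exponential linear unit. Above the
#' top layer sits a classification layer (a convolution of filter size one)
#' whose output per time step is a score for each sound category. The network
#' is fully convolutional: its receptive field
#' `1 + sum((filter_size - 1) * dilation)` must fit inside the input window.
#'
#' @param n_layers Number of convolutional layers.
#' @param units Units per layer (uniform across layers).
#' @param filter_sizes Integer vector of per-layer filter sizes.
#' @param dilations Integer vector of per-layer dilation widths.
#' @param n_categories Number of output categories.
#' @param input_window_samples Input window length in samples; the receptive
#'   field may not exceed it.
#' @return An object of class `"architecture"`.
#' @export
architecture <- function(n_layers, units, filter_sizes, dilations,
                         n_categories, input_window_samples) {
  if (length(filter_sizes) != n_layers || length(dilations) != n_layers)
    stop("filter_sizes and dilations must have one entry per layer")
  if (any(filter_sizes < 1) || any(dilations < 1))
    stop("filter sizes and dilations must be positive")
  arch <- structure(
    list(n_layers = as.integer(n_layers), units = as.integer(units),
         filter_sizes = as.integer(filter_sizes),
         dilations = as.integer(dilations),
         n_categories = as.integer(n_categories),
         input_window_samples = as.integer(input_window_samples)),
    class = "architecture")
  rf <- receptive_field(arch)
  if (rf > input_window_samples)
    stop("receptive field (", rf, ") exceeds input window (",
         input_window_samples, ")")
  arch
}

#' @exportS3Method base::print
print.architecture <- function(x, ...) {
  cat(sprintf("<architecture: %d layers x %d units, %d categories, RF %d / window %d>\n",
              x$n_layers, x$units, x$n_categories, receptive_field(x),
              x$input_window_samples))
  invisible(x)
}

#' Receptive field of an architecture
#'
#' `1 + sum((filter_size - 1) * dilation)` over the layers: the number of
#' input samples that influence a single output time step.
#'
#' @param arch An [architecture()], or a list with `filter_sizes` and
#'   `dilations`.
#' @return Integer number of samples.
#' @export
receptive_field <- function(arch) {
  k <- arch$filter_sizes; d <- arch$dilations
  if (length(k) != length(d)) stop("per-layer lists differ in length")
  if (any(k < 1) || any(d < 1)) stop("filter sizes and dilations must be positive")
  as.integer(1 + sum((k - 1) * d))
}

#' The four best-performing published architectures
#'
#' Thirteen-layer architectures (units per layer, per-layer filter sizes and
#' dilation widths) selected by the two-step search on the everyday-sound
#' corpus; all satisfy the 0.2 s receptive-field constraint at 44.1 kHz
#' (8820 samples).
#'
#' @param n_categories Category count to attach (default 50).
#' @return A list of four [architecture()] objects.
#' @export
table1_architectures <- function(n_categories = 50) {
  spec <- list(
    list(units = 256,
         k = c(5, 3, 6, 5, 2, 7, 8, 8, 7, 4, 4, 6, 5),
         d = c(231, 603, 18, 138, 14, 97, 105, 7, 137, 381, 193, 208, 266)),
    list(units = 512,
         k = c(3, 4, 4, 3, 6, 6, 4, 6, 8, 8, 7, 7, 3),
         d = c(449, 12, 161, 374, 175, 193, 120, 209, 161, 47, 151, 16, 465)),
    list(units = 128,
         k = c(7, 4, 4, 2, 7, 3, 7, 5, 2, 4, 3, 7, 2),
         d = c(42, 125, 341, 603, 96, 410, 44, 269, 747, 152, 528, 122, 823)),
    list(units = 512,
         k = c(3, 7, 2, 7, 7, 4, 5, 5, 3, 8, 8, 8, 2),
         d = c(676, 105, 581, 54, 16, 192, 214, 2, 173, 173, 184, 92, 887)))
  lapply(spec, function(s)
    architecture(13, s$units, s$k, s$d, n_categories, 8820))
}

#' Randomly sample an architecture under the receptive-field constraint
#'
#' Filter sizes are drawn uniformly from `filter_range` and dilation widths
#' are drawn by splitting a random fraction of the receptive-field budget
#' across layers, so the constraint
#' `receptive_field <= input_window_samples` holds by construction.
#' Deterministic for a fixed seed.
#'
#' @param n_layers Number of layers, one of 7, 9, 11, 13 by default.
#' @param input_window_samples Input window in samples.
#' @param rng_seed Integer seed.
#' @param units_choices Allowed units per layer.
#' @param filter_range Inclusive range of filter sizes.
#' @param n_categories Category count.
#' @param allowed_layers Allowed layer counts.
#' @return An [architecture()].
#' @export
sample_architecture <- function(n_layers, input_window_samples, rng_seed,
                                units_choices = c(32, 64, 128, 256, 512),
                                filter_range = c(2, 8), n_categories = 50,
                                allowed_layers = c(7, 9, 11, 13)) {
  if (!n_layers %in% allowed_layers)
    stop("n_layers must be one of ", paste(allowed_layers, collapse = ", "))
  budget <- input_window_samples - 1
  if (budget < n_layers * (filter_range[1] - 1))
    stop("receptive-field constraint unsatisfiable for this window")
  with_seed(rng_seed, {
    units <- if (length(units_choices) == 1L) units_choices else
      sample(units_choices, 1)
    k <- sample(seq(filter_range[1], filter_range[2]), n_layers, replace = TRUE)
    # spend a random fraction of the budget, split Dirichlet-like over layers
    frac <- stats::runif(1, 0.3, 0.95)
    w <- stats::rexp(n_layers)
    w <- w / sum(w)
    d <- pmax(1L, as.integer(floor(w * budget * frac / (k - 1))))
    # repair any overshoot from the pmax floor
    while (sum((k - 1) * d) > budget) {
      i <- which.max((k - 1) * d)
      d[i] <- max(1L, d[i] - 1L)
    }
    architecture(n_layers, units, k, d, n_categories, input_window_samples)
  })
}

elu <- function(z) ifelse(z > 0, z, expm1(z))

# valid dilated convolution: X (C_in x T) -> (C_out x T') with
# T' = T - (k-1)*d; W is a list of k matrices (C_out x C_in)
conv_valid <- function(X, W, b, d) {
  k <- length(W)
  t_out <- ncol(X) - (k - 1) * d
  if (t_out < 1) stop("input too short for this layer")
  Z <- matrix(b, nrow = length(b), ncol = t_out)
  for (j in seq_len(k)) {
    cols <- seq.int((j - 1) * d + 1, length.out = t_out)
    Z <- Z + W[[j]] %*% X[, cols, drop = FALSE]
  }
  Z
}

#' Initialize a model with random weights and zero biases
#'
#' Convolution weights are drawn uniformly with fan-in scaling
#' (`U(-s, s)`, `s = sqrt(1 / (fan_in * filter_size))`); biases are zero.
#' A model in this state is the "nonoptimized" control.
#'
#' @param arch An [architecture()].
#' @param rng_seed Integer seed.
#' @param categories Optional character vector of category labels (length
#'   `n_categories`); may also be set later by [train_model()].
#' @return An object of class `"modsense_model"`.
#' @export
init_model <- function(arch, rng_seed, categories = NULL) {
  stopifnot(inherits(arch, "architecture"))
  if (!is.null(categories) && length(categories) != arch$n_categories)
    stop("categories length must equal n_categories")
  with_seed(rng_seed, {
    W <- vector("list", arch$n_layers)
    b <- vector("list", arch$n_layers)
    c_in <- 1L
    for (i in seq_len(arch$n_layers)) {
      k <- arch$filter_sizes[i]
      s <- sqrt(1 / (c_in * k))
      W[[i]] <- lapply(seq_len(k), function(j)
        matrix(stats::runif(arch$units * c_in, -s, s), arch$units, c_in))
      b[[i]] <- numeric(arch$units)
      c_in <- arch$units
    }
    s <- sqrt(1 / arch$units)
    V <- matrix(stats::runif(arch$n_categories * arch$units, -s, s),
                arch$n_categories, arch$units)
    structure(list(arch = arch, W = W, b = b, V = V,
                   c = numeric(arch$n_categories),
                   categories = categories, frozen = FALSE,
                   training_log = NULL),
              class = "modsense_model")
  })
}

#' @exportS3Method base::print
print.modsense_model <- function(x, ...) {
  cat(sprintf("<modsense_model: %d layers x %d units, %d categories, %s>\n",
              x$arch$n_layers, x$arch$units, x$arch$n_categories,
              if (isTRUE(x$frozen)) "frozen" else "trainable"))
  invisible(x)
}

#' Checksum of a model's parameters
#'
#' Hash of all weights and biases; unchanged by any simulated psychophysical
#' or neurophysiological experiment (the experiments only read activations).
#'
#' @param model A `"modsense_model"`.
#' @return A character hash.
#' @export
model_checksum <- function(model) {
  rlang::hash(list(model$W, model$b, model$V, model$c))
}

#' Run a waveform through the model
#'
#' Valid (unpadded) convolution over the whole clip. Per-layer post-ELU unit
#' activities can be recorded for the simulated experiments; the
#' classification layer itself is never part of the recorded layers.
#'
#' @param model A `"modsense_model"`.
#' @param x A [waveform()] at least as long as the receptive field.
#' @param record_layers Integer vector of layer indices whose activations to
#'   keep (1 = closest to the waveform).
#' @return A list: `logits` (`n_categories x T_out` matrix) and
#'   `activations`, a named list of `units x time` matrices for the
#'   requested layers.
#' @export
forward <- function(model, x, record_layers = integer(0)) {
  arch <- model$arch
  rf <- receptive_field(arch)
  if (length(x) < rf)
    stop("input (", length(x), " samples) shorter than receptive field (", rf, ")")
  if (any(record_layers < 1 | record_layers > arch$n_layers))
    stop("record_layers out of range")
  A <- matrix(as.numeric(x), nrow = 1)
  rec <- list()
  for (i in seq_len(arch$n_layers)) {
    A <- elu(conv_valid(A, model$W[[i]], model$b[[i]], arch$dilations[i]))
    if (i %in% record_layers) rec[[as.character(i)]] <- A
  }
  logits <- sweep(model$V %*% A, 1, model$c, "+")
  list(logits = logits, activations = rec)
}

#' Record a layer's unit activities for a stimulus
#'
#' Convenience wrapper around [forward()] returning just one layer's
#' `units x time` activity matrix.
#'
#' @inheritParams forward
#' @param layer Layer index.
#' @return A numeric matrix (`units x time`).
#' @export
layer_activations <- function(model, x, layer) {
  forward(model, x, record_layers = layer)$activations[[as.character(layer)]]
}

#' Build an observer function from a model layer
#'
#' The psychophysics and neurophysiology simulators consume an *observer*:
#' a function mapping a [waveform()] to a `units x time` activity matrix.
#' This wraps a frozen model layer as such a function; tests also construct
#' synthetic observers directly.
#'
#' @param model A `"modsense_model"`.
#' @param layer Layer index.
#' @return A function `waveform -> matrix`.
#' @export
layer_observer <- function(model, layer) {
  force(model); force(layer)
  function(x) layer_activations(model, x, layer)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# forward over a window whose length equals the receptive field (single
# output step), keeping per-layer activations for backprop
forward_window <- function(model, xwin) {
  arch <- model$arch
  acts <- vector("list", arch$n_layers + 1L)
  acts[[1]] <- matrix(xwin, nrow = 1)
  for (i in seq_len(arch$n_layers)) {
    acts[[i + 1]] <- elu(conv_valid(acts[[i]], model$W[[i]], model$b[[i]],
                                    arch$dilations[i]))
  }
  h <- acts[[arch$n_layers + 1L]]
  logits <- as.numeric(model$V %*% h[, ncol(h), drop = FALSE]) + model$c
  list(acts = acts, logits = logits)
}

# gradients of single-step softmax cross-entropy wrt all parameters
backward_window <- function(model, fw, label_idx) {
  arch <- model$arch
  p <- softmax(fw$logits)
  dlogits <- p
  dlogits[label_idx] <- dlogits[label_idx] - 1
  h_top <- fw$acts[[arch$n_layers + 1L]]
  gV <- dlogits %*% t(h_top[, ncol(h_top), drop = FALSE])
  gc <- dlogits
  dA <- matrix(0, nrow(h_top), ncol(h_top))
  dA[, ncol(h_top)] <- as.numeric(t(model$V) %*% dlogits)
  gW <- vector("list", arch$n_layers)
  gb <- vector("list", arch$n_layers)
  for (i in rev(seq_len(arch$n_layers))) {
    A <- fw$acts[[i + 1]]       # post-ELU output of layer i
    X <- fw$acts[[i]]           # input to layer i
    dZ <- dA * ifelse(A > 0, 1, A + 1)   # ELU'(z) = exp(z) = a + 1 for z <= 0
    gb[[i]] <- rowSums(dZ)
    k <- length(model$W[[i]]); d <- model$arch$dilations[i]
    t_out <- ncol(A)
    gW[[i]] <- vector("list", k)
    dX <- matrix(0, nrow(X), ncol(X))
    for (j in seq_len(k)) {
      cols <- seq.int((j - 1) * d + 1, length.out = t_out)
      gW[[i]][[j]] <- dZ %*% t(X[, cols, drop = FALSE])
      dX[, cols] <- dX[, cols] + t(model$W[[i]][[j]]) %*% dZ
    }
    dA <- dX
  }
  list(gW = gW, gb = gb, gV = gV, gc = gc,
       loss = -log(max(p[label_idx], 1e-12)))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default `1e-4`).
#' @param patience_epochs Early-stopping patience: training stops once
#'   held-out accuracy has not improved for this many consecutive epochs.
#' @param batch_size Clips per parameter update (default 16).
#' @param amplitude_jitter_db During training each clip's amplitude is varied
#'   by a uniform dB offset in `[-jitter, +jitter]` (default 6).
#' @param max_epochs Hard epoch cap (default 500).
#' @param rng_seed Integer seed governing shuffling, window choice and jitter.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(learning_rate = 1e-4, patience_epochs = 16,
                            batch_size = 16, amplitude_jitter_db = 6,
                            max_epochs = 500, rng_seed = 1) {
  stopifnot(learning_rate > 0, patience_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 patience_epochs = as.integer(patience_epochs),
                 batch_size = as.integer(batch_size),
                 amplitude_jitter_db = amplitude_jitter_db,
                 max_epochs = as.integer(max_epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

adam_init <- function(params) lapply(params, function(p) {
  if (is.list(p)) lapply(p, function(q) {
    if (is.list(q)) lapply(q, function(r) r * 0) else q * 0
  }) else p * 0
})

# flatten/apply helpers: parameters live in a nested list
# (W[[layer]][[tap]], b[[layer]], V, c); walk both trees in lockstep
tree_map2 <- function(a, b, f) {
  if (is.list(a)) purrr::map2(a, b, tree_map2, f = f) else f(a, b)
}
tree_map3 <- function(a, b, c, f) {
  if (is.list(a)) purrr::pmap(list(a, b, c), tree_map3, f = f) else f(a, b, c)
}

#' Train a model on a labeled corpus
#'
#' Minimizes single-time-step softmax cross-entropy with Adam over the
#' `"update"` split, evaluating clip-level recognition accuracy on the
#' `"earlystop"` split after every epoch (an epoch is one pass over the
#' update split, one randomly positioned receptive-field window per clip,
#' with per-clip amplitude jitter). Training stops when early-stop accuracy
#' has not improved for `patience_epochs` epochs; the parameters from the
#' best epoch are returned and the model is frozen.
#'
#' @param model A `"modsense_model"` (typically from [init_model()]).
#' @param corpus A corpus tibble with columns `wave` (list of [waveform()]),
#'   `category`, and `split` containing at least `"update"` and
#'   `"earlystop"` rows.
#' @param config A [training_config()].
#' @return A frozen `"modsense_model"` with a `training_log` tibble
#'   (`epoch`, `mean_loss`, `earlystop_accuracy`, `best_so_far`).
#' @export
train_model <- function(model, corpus, config = training_config()) {
  stopifnot(inherits(model, "modsense_model"))
  upd <- corpus[corpus$split == "update", ]
  es <- corpus[corpus$split == "earlystop", ]
  if (nrow(upd) == 0 || nrow(es) == 0)
    stop("corpus must contain nonempty 'update' and 'earlystop' splits")
  cats <- sort(unique(as.character(corpus$category)))
  if (length(cats) != model$arch$n_categories)
    stop("corpus has ", length(cats), " categories but model expects ",
         model$arch$n_categories)
  model$categories <- cats
  rf <- receptive_field(model$arch)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  params <- list(W = model$W, b = model$b, V = model$V, c = model$c)
  m_st <- adam_init(params)
  v_st <- adam_init(params)
  step <- 0L
  best_acc <- -Inf
  best_params <- params
  stale <- 0L
  log <- list()
  upd_labels <- match(as.character(upd$category), cats)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$rng_seed, 11L, epoch),
                     sample(nrow(upd)))
    losses <- numeric(0)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      g_acc <- NULL
      for (ii in idx) {
        wav <- upd$wave[[ii]]
        sd2 <- derive_seed(config$rng_seed, 13L, epoch, ii)
        xwin <- with_seed(sd2, {
          start <- sample.int(length(wav) - rf + 1L, 1)
          jit <- stats::runif(1, -config$amplitude_jitter_db,
                              config$amplitude_jitter_db)
          as.numeric(wav[start:(start + rf - 1L)]) * 10^(jit / 20)
        })
        model$W <- params$W; model$b <- params$b
        model$V <- params$V; model$c <- params$c
        fw <- forward_window(model, xwin)
        bw <- backward_window(model, fw, upd_labels[ii])
        g <- list(W = bw$gW, b = bw$gb, V = bw$gV, c = bw$gc)
        g_acc <- if (is.null(g_acc)) g else tree_map2(g_acc, g, `+`)
        losses <- c(losses, bw$loss)
      }
      g_acc <- tree_map2(g_acc, g_acc, function(a, b) a / length(idx))
      step <- step + 1L
      m_st <- tree_map2(m_st, g_acc, function(m, g) beta1 * m + (1 - beta1) * g)
      v_st <- tree_map2(v_st, g_acc, function(v, g) beta2 * v + (1 - beta2) * g^2)
      corr <- lr * sqrt(1 - beta2^step) / (1 - beta1^step)
      params <- tree_map3(params, m_st, v_st,
                          function(p, m, v) p - corr * m / (sqrt(v) + eps))
    }
    model$W <- params$W; model$b <- params$b
    model$V <- params$V; model$c <- params$c
    acc <- evaluate_recognition(model, es)
    improved <- acc > best_acc
    if (improved) {
      best_acc <- acc
      best_params <- params
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch, mean_loss = mean(losses),
                                   earlystop_accuracy = acc,
                                   best_so_far = best_acc)
    if (stale >= config$patience_epochs) break
  }
  model$W <- best_params$W; model$b <- best_params$b
  model$V <- best_params$V; model$c <- best_params$c
  model$frozen <- TRUE
  model$training_log <- dplyr::bind_rows(log)
  model
}

#' Evaluate clip-level recognition accuracy
#'
#' Runs each clip through the model, averages the classification-layer
#' output over time (or over each annotated span) and scores the argmax
#' category against the label.
#'
#' @param model A `"modsense_model"` with `categories` set.
#' @param corpus Corpus tibble (`wave`, `category`); when `spans` evaluation
#'   is wanted, also a `spans` list-column of data frames with `start`,
#'   `end` (sample indices into the clip) and `category`.
#' @param use_spans Average within annotated spans instead of whole clips.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_recognition <- function(model, corpus, use_spans = FALSE) {
  cats <- model$categories
  if (is.null(cats)) stop("model has no category labels; train it first")
  rf <- receptive_field(model$arch)
  correct <- 0L; total <- 0L
  for (i in seq_len(nrow(corpus))) {
    lg <- forward(model, corpus$wave[[i]])$logits
    if (use_spans) {
      sp <- corpus$spans[[i]]
      for (s in seq_len(nrow(sp))) {
        if (sp$start[s] < 1 || sp$end[s] > length(corpus$wave[[i]]))
          stop("span outside clip")
        # an output column t covers input [t, t + rf - 1]; use columns whose
        # window center falls in the span, else the nearest center
        centers <- seq_len(ncol(lg)) + (rf - 1) / 2
        cols <- which(centers >= sp$start[s] & centers <= sp$end[s])
        if (length(cols) == 0)
          cols <- which.min(abs(centers - (sp$start[s] + sp$end[s]) / 2))
        pred <- cats[which.max(rowMeans(lg[, cols, drop = FALSE]))]
        correct <- correct + (pred == as.character(sp$category[s]))
        total <- total + 1L
      }
    } else {
      pred <- cats[which.max(rowMeans(lg))]
      correct <- correct + (pred == as.character(corpus$category[i]))
      total <- total + 1L
    }
  }
  correct / total
}

#' Two-step architecture search
#'
#' Step 1: for each candidate layer count, sample `n_candidates`
#' architectures and train each with patience `patience1`; rank layer counts
#' by the mean early-stop accuracy of their `best_k` best models and keep the
#' winning count. Step 2: continue training the winners' candidates with the
#' larger patience `patience2` and return the `best_k` best models.
#'
#' @param corpus Corpus tibble (see [train_model()]).
#' @param layer_counts Candidate layer counts.
#' @param n_candidates Architectures sampled per layer count.
#' @param best_k Models averaged/returned per group.
#' @param patience1,patience2 Early-stopping patience for the two steps.
#' @param config Base [training_config()]; its patience is overridden per step.
#' @param rng_seed Integer seed.
#' @param input_window_samples Input window for sampled architectures.
#' @param units_choices,filter_range Passed to [sample_architecture()].
#' @return A list: `models` (the `best_k` frozen models, best first),
#'   `step1` tibble (layer_count, candidate, accuracy), `selected_layers`.
#' @export
architecture_search <- function(corpus, layer_counts = c(7, 9, 11, 13),
                                n_candidates = 20, best_k = 4,
                                patience1 = 32, patience2 = 96,
                                config = training_config(), rng_seed = 1,
                                input_window_samples,
                                units_choices = c(32, 64, 128, 256, 512),
                                filter_range = c(2, 8)) {
  if (n_candidates < best_k) stop("need at least best_k candidates per group")
  n_cat <- length(unique(as.character(corpus$category)))
  step1 <- list(); trained1 <- list()
  for (L in layer_counts) {
    for (cand in seq_len(n_candidates)) {
      sd <- derive_seed(rng_seed, match(L, layer_counts), cand)
      arch <- sample_architecture(L, input_window_samples, sd,
                                  units_choices = units_choices,
                                  filter_range = filter_range,
                                  n_categories = n_cat,
                                  allowed_layers = layer_counts)
      cfg <- config
      cfg$patience_epochs <- as.integer(patience1)
      cfg$rng_seed <- derive_seed(sd, 1L)
      mdl <- train_model(init_model(arch, derive_seed(sd, 2L)), corpus, cfg)
      acc <- max(mdl$training_log$earlystop_accuracy)
      key <- paste(L, cand, sep = "_")
      trained1[[key]] <- mdl
      step1[[key]] <- tibble::tibble(layer_count = L, candidate = cand,
                                     accuracy = acc)
    }
  }
  step1 <- dplyr::bind_rows(step1)
  group_score <- step1 |>
    dplyr::group_by(.data$layer_count) |>
    dplyr::summarise(score = mean(sort(.data$accuracy,
                                       decreasing = TRUE)[seq_len(best_k)]),
                     .groups = "drop")
  sel <- group_score$layer_count[which.max(group_score$score)]
  survivors <- step1[step1$layer_count == sel, ]
  models2 <- list(); acc2 <- numeric(0)
  for (r in seq_len(nrow(survivors))) {
    key <- paste(sel, survivors$candidate[r], sep = "_")
    mdl <- trained1[[key]]
    mdl$frozen <- FALSE
    cfg <- config
    cfg$patience_epochs <- as.integer(patience2)
    cfg$rng_seed <- derive_seed(rng_seed, 3L, survivors$candidate[r])
    mdl <- train_model(mdl, corpus, cfg)
    models2[[key]] <- mdl
    acc2[key] <- max(mdl$training_log$earlystop_accuracy)
  }
  ord <- order(acc2, decreasing = TRUE)[seq_len(min(best_k, length(acc2)))]
  list(models = unname(models2[ord]), step1 = step1, selected_layers = sel)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive holding the architecture, category labels and
#' all weights; numeric precision is preserved (`digits = NA`).
#'
#' @param model A `"modsense_model"`.
#' @param path File path.
#' @return `load_model()` returns the restored model.
#' @export
save_model <- function(model, path) {
  obj <- list(
    arch = unclass(model$arch),
    categories = model$categories,
    frozen = isTRUE(model$frozen),
    W = lapply(model$W, function(lw) lapply(lw, as.numeric)),
    b = model$b,
    V = as.numeric(model$V),
    c = model$c)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- architecture(o$arch$n_layers, o$arch$units, o$arch$filter_sizes,
                       o$arch$dilations, o$arch$n_categories,
                       o$arch$input_window_samples)
  units <- arch$units
  W <- vector("list", arch$n_layers)
  c_in <- 1L
  for (i in seq_len(arch$n_layers)) {
    wi <- o$W[[i]]
    k <- arch$filter_sizes[i]
    # simplifyVector can collapse a layer's equal-length tap vectors into a
    # k x (units * c_in) matrix; recover one weight matrix per tap either way
    taps <- if (is.matrix(wi)) {
      lapply(seq_len(k), function(j) wi[j, ])
    } else {
      lapply(wi, as.numeric)
    }
    W[[i]] <- lapply(taps, function(v) matrix(v, units, c_in))
    c_in <- units
  }
  b <- if (is.matrix(o$b)) {
    lapply(seq_len(arch$n_layers), function(i) as.numeric(o$b[i, ]))
  } else {
    lapply(seq_len(arch$n_layers), function(i) as.numeric(o$b[[i]]))
  }
  structure(list(arch = arch,
                 W = W, b = b,
                 V = matrix(o$V, arch$n_categories, units),
                 c = as.numeric(o$c),
                 categories = o$categories,
                 frozen = isTRUE(o$frozen),
                 training_log = NULL),
            class = "modsense_model")
}
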