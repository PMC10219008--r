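#' Generate the stimuli of one forced-choice trial
#'
#' `n_intervals` stimuli with independent carriers, exactly one of them
#' modulated at the given rate and depth; the modulated position is drawn
#' uniformly.
#'
#' @param cond One row of [am_conditions()].
#' @param rate_hz AM rate.
#' @param depth_db AM depth in dB.
#' @param rng_seed Integer seed.
#' @return A list with `stimuli` (list of [waveform()]s) and
#'   `modulated_index`.
#' @export
xifc_trial <- function(cond, rate_hz, depth_db, rng_seed) {
  cond <- as_condition(cond)
  x <- cond$n_intervals
  mod_pos <- with_seed(derive_seed(rng_seed, 999L), sample.int(x, 1))
  stimuli <- lapply(seq_len(x), function(i)
    make_stimulus(cond, rate_hz, depth_db, modulated = (i == mod_pos),
                  rng_seed = derive_seed(rng_seed, i)))
  list(stimuli = stimuli, modulated_index = mod_pos)
}

# argmax with seeded uniform tie-breaking among near-ties
argmax_tiebreak <- function(v, rng_seed, tol = 1e-9) {
  top <- max(v)
  ties <- which(v >= top - tol * max(1, abs(top)))
  if (length(ties) == 1L) ties else with_seed(rng_seed, sample(ties, 1))
}

# time-averaged unit activities: the per-stimulus feature vector
stimulus_features <- function(observer, wave) {
  act <- observer(wave)
  if (is.null(dim(act))) act <- matrix(act, nrow = 1)
  rowMeans(act)
}

#' Simulate AM detection with a ridge-logistic observer readout
#'
#' Runs `n_trials` forced-choice trials at one (condition, rate, depth).
#' Each stimulus is reduced to the time average of the observed layer's unit
#' activities; an L2-regularized logistic regression is trained to tell
#' modulated from unmodulated stimuli. Trials are scored in an outer 4-fold
#' cross-validation (96 training / 32 held-out trials at the defaults); the
#' ridge penalty is selected in an inner 4-fold cross-validation over a
#' 13-point log-spaced grid (ties prefer stronger regularization). In each
#' held-out trial, the interval with the highest modulated-probability is
#' the response; exact ties are broken uniformly at random.
#'
#' @param observer A function `waveform -> units x time matrix`, e.g.
#'   [layer_observer()].
#' @param cond One row of [am_conditions()].
#' @param rate_hz,depth_db Stimulus parameters.
#' @param n_trials Number of trials (must divide by `n_folds`).
#' @param n_folds Outer (and inner) fold count.
#' @param lambda_grid Ridge penalties to search.
#' @param rng_seed Integer seed.
#' @return Proportion of correct trials.
#' @export
run_xifc_logistic <- function(observer, cond, rate_hz, depth_db,
                              n_trials = 128, n_folds = 4,
                              lambda_grid = 10^seq(3, -3, length.out = 13),
                              rng_seed = 1) {
  cond <- as_condition(cond)
  if (n_trials %% n_folds != 0)
    stop("n_trials (", n_trials, ") must be divisible by n_folds (", n_folds, ")")
  x <- cond$n_intervals
  feats <- vector("list", n_trials)
  labels <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    tr <- xifc_trial(cond, rate_hz, depth_db, derive_seed(rng_seed, 7L, t))
    fl <- lapply(tr$stimuli, function(s) stimulus_features(observer, s))
    feats[[t]] <- do.call(rbind, fl)
    labels[[t]] <- as.integer(seq_len(x) == tr$modulated_index)
  }
  n_units <- ncol(feats[[1]])
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fold_of <- rep(seq_len(n_folds), each = n_trials / n_folds)
  correct <- logical(n_trials)
  for (fold in seq_len(n_folds)) {
    train_tr <- which(fold_of != fold)
    test_tr <- which(fold_of == fold)
    Xtr <- do.call(rbind, feats[train_tr])
    ytr <- unlist(labels[train_tr])
    lam <- select_ridge_lambda(feats[train_tr], labels[train_tr],
                               lambda_grid, n_folds)
    # glmnet warns about small per-class counts at toy trial numbers;
    # the fit itself is well defined
    fit <- suppressWarnings(
      glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                     lambda = lambda_grid))
    for (t in test_tr) {
      p <- as.numeric(stats::predict(fit, feats[[t]], s = lam,
                                     type = "response"))
      resp <- argmax_tiebreak(p, derive_seed(rng_seed, 17L, t))
      correct[t] <- labels[[t]][resp] == 1L
    }
  }
  mean(correct)
}

# inner CV over trials: pick the ridge penalty maximizing trial-level
# accuracy; ties go to the strongest penalty (grid is descending)
select_ridge_lambda <- function(feats, labels, lambda_grid, n_folds) {
  n <- length(feats)
  fold_of <- rep(seq_len(n_folds), length.out = n)
  acc <- matrix(0, n_folds, length(lambda_grid))
  for (fold in seq_len(n_folds)) {
    tr <- which(fold_of != fold); te <- which(fold_of == fold)
    fit <- suppressWarnings(
      glmnet::glmnet(do.call(rbind, feats[tr]), unlist(labels[tr]),
                     family = "binomial", alpha = 0, lambda = lambda_grid))
    for (t in te) {
      p <- stats::predict(fit, feats[[t]], s = lambda_grid, type = "response")
      hit <- apply(p, 2, function(col)
        labels[[t]][which.max(col)] == 1L)
      acc[fold, ] <- acc[fold, ] + hit / length(te)
    }
  }
  mean_acc <- colMeans(acc)
  lambda_grid[which.max(mean_acc)]  # first max = largest lambda
}

#' Build an AM-detection template from a model layer
#'
#' Average unit activities over `n` independent fully modulated stimuli
#' minus the average over `n` independent unmodulated stimuli, elementwise
#' over units and time.
#'
#' @inheritParams run_xifc_logistic
#' @param rate_hz AM rate of the fully modulated stimuli.
#' @param n Stimuli per class (default 128).
#' @return A list of class `"am_template"`: `values` (units x time matrix),
#'   `condition`, `rate_hz`.
#' @export
make_template <- function(observer, cond, rate_hz, n = 128, rng_seed = 1) {
  cond <- as_condition(cond)
  acc_mod <- NULL; acc_unm <- NULL
  for (i in seq_len(n)) {
    sm <- make_stimulus(cond, rate_hz, 0, TRUE, derive_seed(rng_seed, 21L, i))
    su <- make_stimulus(cond, rate_hz, -Inf, FALSE, derive_seed(rng_seed, 22L, i))
    am <- observer(sm); au <- observer(su)
    acc_mod <- if (is.null(acc_mod)) am else acc_mod + am
    acc_unm <- if (is.null(acc_unm)) au else acc_unm + au
  }
  structure(list(values = acc_mod / n - acc_unm / n,
                 condition = cond$condition, rate_hz = rate_hz),
            class = "am_template")
}

#' Simulate AM detection with a template-correlation observer
#'
#' Scores each interval by the non-normalized correlation (dot product over
#' units and time) between the layer's response and the template; the
#' interval with the largest score is the response, ties broken uniformly.
#'
#' @inheritParams run_xifc_logistic
#' @param template An `"am_template"` from [make_template()], built for the
#'   same observer, condition and rate.
#' @return Proportion of correct trials.
#' @export
run_xifc_template <- function(observer, template, cond, rate_hz, depth_db,
                              n_trials = 128, rng_seed = 1) {
  cond <- as_condition(cond)
  if (!inherits(template, "am_template")) stop("template must be an am_template")
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    tr <- xifc_trial(cond, rate_hz, depth_db, derive_seed(rng_seed, 31L, t))
    score <- vapply(tr$stimuli, function(s) {
      act <- observer(s)
      if (!all(dim(act) == dim(template$values)))
        stop("activation shape ", paste(dim(act), collapse = "x"),
             " does not match template ",
             paste(dim(template$values), collapse = "x"))
      sum(act * template$values)
    }, numeric(1))
    resp <- argmax_tiebreak(score, derive_seed(rng_seed, 37L, t))
    correct[t] <- resp == tr$modulated_index
  }
  mean(correct)
}

psychometric_curve <- function(m, gamma, alpha, beta, lambda) {
  gamma + (1 - gamma) * (1 + exp(-(m - alpha) / beta))^(-lambda)
}

#' Fit an asymmetric sigmoid psychometric function
#'
#' Fits `psi(m) = gamma + (1 - gamma) * (1 + exp(-(m - alpha)/beta))^-lambda`
#' (a Richards-type asymmetric sigmoid with the guess rate pinned at
#' `1 / n_intervals`) to proportion-correct data by least squares with
#' multi-start `nlminb`. The detection threshold is the depth at which the
#' fitted curve crosses 70.7% correct; when the curve never crosses inside
#' the tested range the threshold is clipped to the range minimum (curve
#' entirely above) or maximum (curve entirely below) and flagged.
#'
#' @param data A data frame with columns `depth_db` and `prop_correct`
#'   (and optionally `n_trials`).
#' @param n_intervals Number of forced-choice intervals (guess rate
#'   `1 / n_intervals`).
#' @param target Correct proportion defining the threshold (default 0.707).
#' @return An object of class `"psychometric_fit"`: parameters, `threshold_db`,
#'   `clipped`, `converged`, and the data.
#' @export
fit_psychometric <- function(data, n_intervals, target = 0.707) {
  stopifnot(all(c("depth_db", "prop_correct") %in% names(data)))
  if (nrow(data) < 4) stop("need at least 4 depth points")
  m <- data$depth_db; p <- data$prop_correct
  gamma <- 1 / n_intervals
  obj <- function(par) {
    psi <- psychometric_curve(m, gamma, par[1], exp(par[2]), exp(par[3]))
    sum((psi - p)^2)
  }
  lo <- min(m); hi <- max(m)
  starts <- expand.grid(alpha = stats::quantile(m, c(0.1, 0.35, 0.65, 0.9)),
                        lbeta = log(c(2, 6, 14)),
                        llambda = log(c(0.5, 1, 2)))
  best <- NULL
  converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(as.numeric(starts[s, ]), obj,
                    lower = c(lo - 60, log(0.1), log(0.05)),
                    upper = c(hi + 60, log(200), log(20))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
      converged <- TRUE
    }
  }
  if (!converged) {
    # fallback: no usable fit; clip by where the raw data sit
    thr <- if (mean(p) >= target) lo else hi
    return(structure(list(gamma = gamma, alpha = NA_real_, beta = NA_real_,
                          lambda = NA_real_, threshold_db = thr,
                          clipped = TRUE, converged = FALSE,
                          target = target, data = tibble::as_tibble(data)),
                     class = "psychometric_fit"))
  }
  alpha <- best$par[1]; beta <- exp(best$par[2]); lambda <- exp(best$par[3])
  psi_lo <- psychometric_curve(lo, gamma, alpha, beta, lambda)
  psi_hi <- psychometric_curve(hi, gamma, alpha, beta, lambda)
  if (psi_lo >= target) {
    thr <- lo; clipped <- TRUE
  } else if (psi_hi <= target) {
    thr <- hi; clipped <- TRUE
  } else {
    thr <- stats::uniroot(function(mm)
      psychometric_curve(mm, gamma, alpha, beta, lambda) - target,
      lower = lo, upper = hi, tol = 1e-8)$root
    clipped <- FALSE
  }
  structure(list(gamma = gamma, alpha = alpha, beta = beta, lambda = lambda,
                 threshold_db = thr, clipped = clipped, converged = TRUE,
                 target = target, data = tibble::as_tibble(data)),
            class = "psychometric_fit")
}

#' @exportS3Method base::print
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit: threshold %.2f dB%s (target %.3f, gamma %.3f)>\n",
              x$threshold_db, if (x$clipped) " [clipped]" else "", x$target,
              x$gamma))
  invisible(x)
}

#' Measure a temporal modulation transfer function
#'
#' Runs the constant-stimulus forced-choice experiment at each AM rate of a
#' condition: the proportion of correct trials is computed independently at
#' every depth of the condition's grid, a psychometric function is fitted,
#' and the 70.7% threshold extracted. Deterministic under a fixed seed.
#'
#' @inheritParams run_xifc_logistic
#' @param detector `"logistic"` (time-averaged activities + ridge logistic
#'   readout) or `"template"` (dot-product correlation with a
#'   modulated-minus-unmodulated template).
#' @param rates_hz AM rates; default the condition's 8 log-spaced rates.
#' @param depths_db Depth grid; default the condition's grid.
#' @param layer Optional layer label carried into the output.
#' @return An object of class `"tmtf"`: tibble `thresholds` (columns
#'   `condition`, `layer`, `detector`, `rate_hz`, `threshold_db`, `clipped`),
#'   tibble `psychometric` (raw proportions), and the fits.
#' @export
measure_tmtf <- function(observer, cond, detector = c("logistic", "template"),
                         n_trials = 128, rng_seed = 1,
                         rates_hz = NULL, depths_db = NULL, layer = NA) {
  cond <- as_condition(cond)
  detector <- match.arg(detector)
  if (is.null(rates_hz)) rates_hz <- condition_rates(cond)
  if (is.null(depths_db)) depths_db <- condition_depths(cond)
  rows <- list(); raw <- list(); fits <- list()
  for (ri in seq_along(rates_hz)) {
    f <- rates_hz[ri]
    template <- if (detector == "template")
      make_template(observer, cond, f, n = n_trials,
                    rng_seed = derive_seed(rng_seed, 41L, ri))
    props <- vapply(seq_along(depths_db), function(di) {
      sd <- derive_seed(rng_seed, 43L, ri, di)
      if (detector == "logistic") {
        run_xifc_logistic(observer, cond, f, depths_db[di],
                          n_trials = n_trials, rng_seed = sd)
      } else {
        run_xifc_template(observer, template, cond, f, depths_db[di],
                          n_trials = n_trials, rng_seed = sd)
      }
    }, numeric(1))
    pdat <- tibble::tibble(depth_db = depths_db, prop_correct = props,
                           n_trials = n_trials)
    fit <- fit_psychometric(pdat, cond$n_intervals)
    fits[[ri]] <- fit
    raw[[ri]] <- dplyr::mutate(pdat, rate_hz = f)
    rows[[ri]] <- tibble::tibble(condition = cond$condition, layer = layer,
                                 detector = detector, rate_hz = f,
                                 threshold_db = fit$threshold_db,
                                 clipped = fit$clipped)
  }
  structure(list(thresholds = dplyr::bind_rows(rows),
                 psychometric = dplyr::bind_rows(raw),
                 fits = fits, condition = cond$condition,
                 detector = detector, layer = layer),
            class = "tmtf")
}

#' @exportS3Method base::print
print.tmtf <- function(x, ...) {
  cat(sprintf("<tmtf: condition %s, detector %s, layer %s>\n",
              x$condition, x$detector, as.character(x$layer)))
  print(x$thresholds)
  invisible(x)
}
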