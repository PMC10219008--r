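#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a psychometric fit
#'
#' @param x A `"psychometric_fit"`.
#' @param ... Unused.
#' @return One row per fitted parameter (`term`, `estimate`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("gamma", "alpha", "beta", "lambda"),
                 estimate = c(x$gamma, x$alpha, x$beta, x$lambda))
}

#' @rdname tidy.psychometric_fit
#' @return `glance()`: a one-row summary with the threshold, clipping and
#'   convergence flags, and residual sum of squares.
#' @export
glance.psychometric_fit <- function(x, ...) {
  rss <- if (x$converged) {
    sum((psychometric_curve(x$data$depth_db, x$gamma, x$alpha, x$beta,
                            x$lambda) - x$data$prop_correct)^2)
  } else NA_real_
  tibble::tibble(threshold_db = x$threshold_db, clipped = x$clipped,
                 converged = x$converged, rss = rss,
                 n_depths = nrow(x$data))
}

#' Tidy a measured TMTF
#'
#' @param x A `"tmtf"` object.
#' @param ... Unused.
#' @return The per-rate threshold tibble.
#' @export
tidy.tmtf <- function(x, ...) x$thresholds

#' @rdname tidy.tmtf
#' @export
glance.tmtf <- function(x, ...) {
  tibble::tibble(condition = x$condition, detector = x$detector,
                 layer = x$layer, n_rates = nrow(x$thresholds),
                 n_clipped = sum(x$thresholds$clipped),
                 min_threshold_db = min(x$thresholds$threshold_db),
                 max_threshold_db = max(x$thresholds$threshold_db))
}

#' Tidy a trained model
#'
#' @param x A `"modsense_model"`.
#' @param ... Unused.
#' @return The per-epoch training log.
#' @export
tidy.modsense_model <- function(x, ...) {
  if (is.null(x$training_log)) {
    tibble::tibble(epoch = integer(), mean_loss = numeric(),
                   earlystop_accuracy = numeric(), best_so_far = numeric())
  } else {
    x$training_log
  }
}

#' @rdname tidy.modsense_model
#' @export
glance.modsense_model <- function(x, ...) {
  n_par <- sum(vapply(x$W, function(lw)
    sum(vapply(lw, length, integer(1))), integer(1))) +
    sum(lengths(x$b)) + length(x$V) + length(x$c)
  tibble::tibble(n_layers = x$arch$n_layers, units = x$arch$units,
                 n_categories = x$arch$n_categories,
                 receptive_field = receptive_field(x$arch),
                 n_parameters = n_par, frozen = isTRUE(x$frozen),
                 epochs_trained = if (is.null(x$training_log)) 0L else
                   nrow(x$training_log),
                 best_earlystop_accuracy = if (is.null(x$training_log))
                   NA_real_ else max(x$training_log$earlystop_accuracy))
}
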