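#' Plot a measured TMTF
#'
#' Detection threshold against AM rate on a log axis; clipped thresholds are
#' drawn as open symbols.
#'
#' @param object A `"tmtf"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tmtf <- function(object, ...) {
  d <- object$thresholds
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rate_hz, y = .data$threshold_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$clipped), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "AM rate (Hz)", y = "Detection threshold (dB)",
                  shape = "clipped",
                  title = sprintf("TMTF: %s, %s detector, layer %s",
                                  object$condition, object$detector,
                                  as.character(object$layer))) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' @param object A `"psychometric_fit"`.
#' @param ... Unused.
#' @return A ggplot of proportion correct against depth with the fitted
#'   curve and the threshold.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$depth_db,
                                       y = .data$prop_correct)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$target, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$threshold_db,
                        linetype = "dotted") +
    ggplot2::labs(x = "AM depth (dB)", y = "Proportion correct") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      depth_db = seq(min(d$depth_db), max(d$depth_db), length.out = 200))
    grid$prop_correct <- psychometric_curve(grid$depth_db, object$gamma,
                                            object$alpha, object$beta,
                                            object$lambda)
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}

#' Plot unit AM tuning curves
#'
#' @param object A `"tuning_curves"` tibble from [measure_tuning()].
#' @param coding `"rate"`, `"sync"`, or both.
#' @param ... Unused.
#' @return A ggplot, one line per unit, faceted by coding.
#' @export
autoplot.tuning_curves <- function(object, coding = c("rate", "sync"), ...) {
  coding <- match.arg(coding, several.ok = TRUE)
  d <- object |>
    tidyr::pivot_longer(c("rate_tuning", "sync_tuning"), names_to = "coding",
                        values_to = "value") |>
    dplyr::mutate(coding = sub("_tuning$", "", .data$coding)) |>
    dplyr::filter(.data$coding %in% !!coding)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rate_hz, y = .data$value,
                                  group = .data$unit)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~coding, scales = "free_y") +
    ggplot2::labs(x = "AM rate (Hz)", y = "Tuning value") +
    ggplot2::theme_minimal()
}

#' Plot a layer-region similarity matrix
#'
#' @param object A `"layer_region_similarity"` tibble from
#'   [layer_region_map()].
#' @param ... Unused.
#' @return A ggplot heat map (regions ordered periphery to center).
#' @export
autoplot.layer_region_similarity <- function(object, ...) {
  order_regions <- c("AN", "CN", "SOC", "NLL", "IC", "MGB", "AC")
  d <- dplyr::mutate(object, region = factor(
    .data$region, levels = intersect(order_regions, unique(.data$region))))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$layer), y = .data$region,
                                  fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Layer", y = "Brain region", fill = "1 - KS") +
    ggplot2::theme_minimal()
}

#' Plot a layerwise similarity report
#'
#' @param object A `"similarity_report"` from [compare_tmtf()].
#' @param ... Unused.
#' @return A ggplot of the three indices against layer.
#' @export
autoplot.similarity_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("pattern_similarity", "discrepancy_db",
                                     "net_difference_db"),
                           names_to = "index", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$layer, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Layer", y = NULL) +
    ggplot2::theme_minimal()
}
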