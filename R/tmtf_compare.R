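#' Average reference TMTFs onto a target rate grid
#'
#' Per condition, each subject's (or each model's) TMTF is interpolated
#' linearly along log2 AM rate onto the target rates and the interpolated
#' thresholds are averaged. No extrapolation is performed: target rates
#' outside a subject's span are clamped to the nearest endpoint and flagged.
#'
#' @param ref A tibble with columns `condition`, `subject`, `rate_hz`,
#'   `threshold_db` (one row per subject and rate).
#' @param target_rates Either a numeric vector applied to every condition or
#'   a tibble with `condition` and `rate_hz`.
#' @return A tibble `condition`, `rate_hz`, `threshold_db`, `clamped`.
#' @export
average_reference <- function(ref, target_rates) {
  stopifnot(all(c("condition", "subject", "rate_hz", "threshold_db") %in%
                  names(ref)))
  if (nrow(ref) == 0) stop("empty reference")
  if (is.numeric(target_rates)) {
    target_rates <- tidyr::expand_grid(condition = unique(ref$condition),
                                       rate_hz = target_rates)
  }
  ref |>
    dplyr::group_by(.data$condition, .data$subject) |>
    dplyr::group_modify(function(d, key) {
      tr <- target_rates$rate_hz[target_rates$condition == key$condition]
      if (length(tr) == 0) return(tibble::tibble())
      lx <- log2(d$rate_hz)
      ord <- order(lx)
      yi <- stats::approx(lx[ord], d$threshold_db[ord], xout = log2(tr),
                          rule = 2, ties = "ordered")$y
      tibble::tibble(rate_hz = tr, threshold_db = yi,
                     clamped = log2(tr) < min(lx) | log2(tr) > max(lx))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$condition, .data$rate_hz) |>
    dplyr::summarise(threshold_db = mean(.data$threshold_db),
                     clamped = any(.data$clamped), .groups = "drop")
}

check_pooled <- function(model_pooled, human_pooled) {
  if (length(model_pooled) != length(human_pooled))
    stop("pooled vectors differ in length (", length(model_pooled), " vs ",
         length(human_pooled), ")")
  invisible(NULL)
}

#' TMTF similarity indices
#'
#' Computed over model and reference thresholds pooled across all conditions
#' and rates:
#' * `pattern_similarity()` — Pearson correlation of the pooled TMTFs
#'   (shape similarity, scale-free).
#' * `discrepancy()` — RMS deviation in dB (absolute dissimilarity).
#' * `net_difference()` — mean signed deviation in dB; positive means the
#'   model's thresholds are higher (less sensitive) than the reference.
#'
#' The identity `discrepancy^2 = net_difference^2 + var_p(differences)`
#' (population variance) holds exactly.
#'
#' @param model_pooled,human_pooled Equal-length numeric vectors of pooled
#'   thresholds in dB.
#' @return A scalar; `pattern_similarity()` returns `NA` when either vector
#'   has zero variance.
#' @export
pattern_similarity <- function(model_pooled, human_pooled) {
  check_pooled(model_pooled, human_pooled)
  if (stats::sd(model_pooled) == 0 || stats::sd(human_pooled) == 0)
    return(NA_real_)
  stats::cor(model_pooled, human_pooled)
}

#' @rdname pattern_similarity
#' @export
discrepancy <- function(model_pooled, human_pooled) {
  check_pooled(model_pooled, human_pooled)
  sqrt(mean((model_pooled - human_pooled)^2))
}

#' @rdname pattern_similarity
#' @export
net_difference <- function(model_pooled, human_pooled) {
  check_pooled(model_pooled, human_pooled)
  mean(model_pooled - human_pooled)
}

#' Compare model TMTFs with a human reference
#'
#' Pools thresholds across conditions and rates (matching rows by condition
#' and rate after averaging the reference onto the model's rate grid) and
#' computes the three indices per layer.
#'
#' @param model_tmtf A tibble of model thresholds with columns `layer`,
#'   `condition`, `rate_hz`, `threshold_db` (e.g. bound rows of
#'   [measure_tmtf()] results).
#' @param reference A subject-level reference tibble (see
#'   [average_reference()]), or an already-averaged tibble with `condition`,
#'   `rate_hz`, `threshold_db` and no `subject` column.
#' @return A tibble of class `"similarity_report"`: one row per layer with
#'   `pattern_similarity`, `discrepancy_db`, `net_difference_db`, `n_points`.
#' @export
compare_tmtf <- function(model_tmtf, reference) {
  stopifnot(all(c("layer", "condition", "rate_hz", "threshold_db") %in%
                  names(model_tmtf)))
  target <- dplyr::distinct(model_tmtf, .data$condition, .data$rate_hz)
  ref_avg <- if ("subject" %in% names(reference)) {
    average_reference(reference, target)
  } else {
    reference
  }
  joined <- dplyr::inner_join(
    model_tmtf,
    dplyr::select(ref_avg, "condition", "rate_hz",
                  ref_threshold_db = "threshold_db"),
    by = c("condition", "rate_hz"))
  if (nrow(joined) == 0) stop("no overlapping (condition, rate) points")
  out <- joined |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      pattern_similarity = pattern_similarity(.data$threshold_db,
                                              .data$ref_threshold_db),
      discrepancy_db = discrepancy(.data$threshold_db, .data$ref_threshold_db),
      net_difference_db = net_difference(.data$threshold_db,
                                         .data$ref_threshold_db),
      n_points = dplyr::n(), .groups = "drop")
  class(out) <- c("similarity_report", class(out))
  out
}

#' Correlate recognition accuracy with TMTF similarity across models
#'
#' Per layer, the Pearson correlation between per-model recognition accuracy
#' and a per-model, per-layer similarity index, with p values Bonferroni
#' corrected for the number of layers (capped at 1). Degenerate variance
#' yields `NA`.
#'
#' @param accuracies Tibble with `model` and `accuracy` (one row per model).
#' @param indices Tibble with `model`, `layer` and `index` (the similarity
#'   index value for that model and layer).
#' @return Tibble `layer`, `r`, `p_raw`, `p_bonferroni`, `n_models`.
#' @export
accuracy_similarity_correlation <- function(accuracies, indices) {
  stopifnot(all(c("model", "accuracy") %in% names(accuracies)),
            all(c("model", "layer", "index") %in% names(indices)))
  if (nrow(accuracies) < 3) stop("need at least 3 models")
  joined <- dplyr::inner_join(indices, accuracies, by = "model")
  n_layers <- dplyr::n_distinct(joined$layer)
  joined |>
    dplyr::group_by(.data$layer) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || stats::sd(d$accuracy) == 0 || stats::sd(d$index) == 0)
        return(tibble::tibble(r = NA_real_, p_raw = NA_real_,
                              p_bonferroni = NA_real_, n_models = nrow(d)))
      ct <- stats::cor.test(d$accuracy, d$index)
      tibble::tibble(r = unname(ct$estimate), p_raw = ct$p.value,
                     p_bonferroni = min(1, ct$p.value * n_layers),
                     n_models = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Synthetic human-like reference TMTFs
#'
#' A stand-in for literature TMTF data used by the tests and demos: for
#' broadband-carrier conditions thresholds follow a low-pass form (rising
#' above a corner rate); for narrowband carriers a high-pass form (falling
#' with rate, with the corner tied to the carrier bandwidth). Three synthetic
#' subjects per condition differ by small offsets. These are not measured
#' human values; the CSV schema (`condition`, `subject`, `rate_hz`,
#' `threshold_db`) is the one expected from real reference data.
#'
#' @param conditions An [am_conditions()] tibble.
#' @param n_subjects Synthetic subjects per condition.
#' @return A subject-level reference tibble.
#' @export
synthetic_human_reference <- function(conditions = am_conditions(),
                                      n_subjects = 3) {
  purrr::pmap_dfr(conditions, function(...) {
    cond <- list(...)
    rates <- condition_rates(cond)
    base <- if (is.finite(cond$carrier_bandwidth_hz)) {
      # high-pass: hardest (highest threshold) near the carrier bandwidth
      corner <- max(cond$carrier_bandwidth_hz, 4)
      -10 - 12 * pmax(0, log2(rates / corner)) +
        6 * pmax(0, 1 - abs(log2(rates / corner)) / 2)
    } else {
      # low-pass: flat floor then rising ~ 4 dB/octave above 16 Hz
      -22 + 4 * pmax(0, log2(rates / 16))
    }
    base <- pmin(base, 0)
    purrr::map_dfr(seq_len(n_subjects), function(s)
      tibble::tibble(condition = cond$condition, subject = paste0("s", s),
                     rate_hz = rates,
                     threshold_db = pmin(base + (s - (n_subjects + 1) / 2) * 1.5,
                                         0)))
  })
}

#' Read a reference TMTF CSV file
#'
#' @param path CSV path with columns `condition`, `subject`, `rate_hz`,
#'   `threshold_db`. A synthetic demonstration fixture ships with the
#'   package at
#'   `system.file("extdata", "human_tmtf_synthetic.csv", package = "modsense")`.
#' @return A tibble.
#' @export
read_reference_tmtf <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "subject", "rate_hz", "threshold_db")
  if (!all(need %in% names(d)))
    stop("reference CSV must have columns ", paste(need, collapse = ", "))
  tibble::as_tibble(d)
}
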