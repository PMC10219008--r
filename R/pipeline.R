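#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end experiment (corpus -> training ->
#' simulated psychophysics -> human comparison -> simulated neurophysiology)
#' into one serializable list. The defaults describe a small demonstration
#' run; pass a [synthetic_corpus_spec()] and larger budgets for real
#' experiments. A global seed fans out deterministically to per-stage seeds.
#'
#' @param corpus_spec A [synthetic_corpus_spec()].
#' @param degrade_mode Optional chimera mode applied to training audio
#'   (`"env1"`, `"envN"`, `"tfs1"`, `"tfsN"`); detection stimuli are never
#'   degraded.
#' @param n_layers,units Architecture of the trained model.
#' @param filter_sizes,dilations Optional explicit architecture; sampled
#'   under the receptive-field constraint when `NULL`.
#' @param input_window_s Input window in seconds (default 0.2).
#' @param training A [training_config()].
#' @param conditions Names of the stimulus conditions to test.
#' @param detector `"logistic"` or `"template"`.
#' @param n_trials Trials per depth.
#' @param n_rates AM rates per condition.
#' @param depth_step_db Optional override of the conditions' depth-grid step
#'   (dB); `NULL` keeps each condition's default.
#' @param layers Layers to run psychophysics/neurophysiology on; `NULL`
#'   means all.
#' @param reference_tmtf `"synthetic"` or a CSV path (see
#'   [read_reference_tmtf()]).
#' @param reference_regions `"synthetic"` or a CSV path (see
#'   [read_region_reference()]).
#' @param neurophys_rates Probe rates for tuning measurement.
#' @param neurophys_repeats Carrier repeats per probe rate.
#' @param seed Global seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(corpus_spec = synthetic_corpus_spec(
                         n_categories = 3, clips_per_category = 12,
                         sample_rate_hz = 8000, clip_duration_s = 0.5,
                         mod_center_hz = c(8, 32, 128)),
                       degrade_mode = NULL,
                       n_layers = 3, units = 32,
                       filter_sizes = NULL, dilations = NULL,
                       input_window_s = 0.2,
                       training = training_config(),
                       conditions = "bb_short", detector = "logistic",
                       n_trials = 16, n_rates = 2, depth_step_db = NULL,
                       layers = NULL,
                       reference_tmtf = "synthetic",
                       reference_regions = "synthetic",
                       neurophys_rates = 2^seq(2, 8, length.out = 6),
                       neurophys_repeats = 3,
                       seed = 1) {
  structure(list(corpus_spec = corpus_spec, degrade_mode = degrade_mode,
                 n_layers = n_layers, units = units,
                 filter_sizes = filter_sizes, dilations = dilations,
                 input_window_s = input_window_s, training = training,
                 conditions = conditions, detector = detector,
                 n_trials = n_trials, n_rates = n_rates,
                 depth_step_db = depth_step_db, layers = layers,
                 reference_tmtf = reference_tmtf,
                 reference_regions = reference_regions,
                 neurophys_rates = neurophys_rates,
                 neurophys_repeats = neurophys_repeats,
                 seed = as.integer(seed)),
            class = "run_config")
}

validate_run_config <- function(config) {
  if (!is.null(config$reference_tmtf) && config$reference_tmtf != "synthetic" &&
      !file.exists(config$reference_tmtf))
    stop("configuration error: reference TMTF CSV not found: ",
         config$reference_tmtf)
  if (!is.null(config$reference_regions) &&
      config$reference_regions != "synthetic" &&
      !file.exists(config$reference_regions))
    stop("configuration error: region reference CSV not found: ",
         config$reference_regions)
  known <- am_conditions()$condition
  bad <- setdiff(config$conditions, known)
  if (length(bad) > 0)
    stop("configuration error: unknown conditions: ", paste(bad, collapse = ", "))
  invisible(config)
}

stage_msg <- function(log_path, stage, text) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, text)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full experiment pipeline
#'
#' Executes the staged experiment and writes every artifact into `out_dir`:
#' the serialized config (`config.yaml`), corpus manifest, model checkpoint
#' and training log, TMTF and raw psychometric CSVs, the human-comparison
#' report (`similarity.json`), tuning and characteristics CSVs, and the
#' layer-region similarity report (`region_similarity.json`). Re-running an
#' identical config reproduces identical tabular outputs. Each stage only
#' consumes artifacts of earlier stages.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must not require overwriting an
#'   existing run unless `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing directory.
#' @return The output directory path, invisibly; the collected results as
#'   the attribute `"results"`.
#' @export
run_experiment <- function(config, out_dir, overwrite = FALSE) {
  validate_run_config(config)
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)) > 0)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  cfg_ser <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(cfg_ser, file.path(out_dir, "config.yaml"))

  # stage 1: corpus --------------------------------------------------------
  stage_msg(log_path, "corpus", "generating synthetic corpus")
  spec <- config$corpus_spec
  spec$rng_seed <- derive_seed(config$seed, 1L)
  corpus <- generate_corpus(spec)
  if (!is.null(config$degrade_mode)) {
    stage_msg(log_path, "corpus", paste("degrading training audio:",
                                        config$degrade_mode))
    train_rows <- corpus$split != "validation"
    deg <- degraded_corpus(corpus[train_rows, ], config$degrade_mode,
                           rng_seed = derive_seed(config$seed, 2L))
    corpus$wave[train_rows] <- deg$wave
  }
  utils::write.csv(dplyr::select(corpus, -"wave"),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)

  # stage 2: model ---------------------------------------------------------
  sr <- spec$sample_rate_hz
  window <- round(config$input_window_s * sr)
  arch <- if (is.null(config$filter_sizes)) {
    sample_architecture(config$n_layers, window,
                        derive_seed(config$seed, 3L),
                        units_choices = config$units,
                        n_categories = spec$n_categories,
                        allowed_layers = config$n_layers)
  } else {
    architecture(config$n_layers, config$units, config$filter_sizes,
                 config$dilations, spec$n_categories, window)
  }
  stage_msg(log_path, "train", sprintf("training %d-layer model (RF %d)",
                                       arch$n_layers, receptive_field(arch)))
  tcfg <- config$training
  tcfg$rng_seed <- derive_seed(config$seed, 4L)
  model <- train_model(init_model(arch, derive_seed(config$seed, 5L)),
                       corpus, tcfg)
  save_model(model, file.path(out_dir, "model.json"))
  utils::write.csv(model$training_log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  val_acc <- evaluate_recognition(model, corpus[corpus$split == "validation", ])
  jsonlite::write_json(list(validation_accuracy = val_acc,
                            chance_level = 1 / spec$n_categories),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_msg(log_path, "train", sprintf("validation accuracy %.3f", val_acc))

  # stage 3: psychophysics -------------------------------------------------
  layers <- if (is.null(config$layers)) seq_len(arch$n_layers) else config$layers
  conds <- am_conditions(sample_rate_hz = sr, target_rms = spec$target_rms)
  conds <- conds[conds$condition %in% config$conditions, ]
  conds$n_rates <- as.integer(config$n_rates)
  if (!is.null(config$depth_step_db))
    conds$depth_step_db <- config$depth_step_db
  tmtfs <- list()
  for (li in layers) {
    obs <- layer_observer(model, li)
    for (ci in seq_len(nrow(conds))) {
      stage_msg(log_path, "tmtf",
                sprintf("layer %d, condition %s", li, conds$condition[ci]))
      tm <- measure_tmtf(obs, conds[ci, ], detector = config$detector,
                         n_trials = config$n_trials,
                         rng_seed = derive_seed(config$seed, 6L, li, ci),
                         layer = li)
      tmtfs[[paste(li, ci)]] <- tm
    }
  }
  tmtf_tbl <- dplyr::bind_rows(purrr::map(tmtfs, "thresholds"))
  psy_tbl <- dplyr::bind_rows(purrr::imap(tmtfs, function(tm, key)
    dplyr::mutate(tm$psychometric, layer = tm$layer, condition = tm$condition)))
  utils::write.csv(tmtf_tbl, file.path(out_dir, "tmtf.csv"), row.names = FALSE)
  utils::write.csv(psy_tbl, file.path(out_dir, "psychometric.csv"),
                   row.names = FALSE)

  # stage 4: human comparison ----------------------------------------------
  stage_msg(log_path, "compare", "comparing with reference TMTFs")
  ref <- if (identical(config$reference_tmtf, "synthetic")) {
    synthetic_human_reference(conds)
  } else {
    read_reference_tmtf(config$reference_tmtf)
  }
  report <- compare_tmtf(tmtf_tbl, ref)
  jsonlite::write_json(
    purrr::set_names(
      purrr::map(seq_len(nrow(report)), function(i)
        list(pattern_similarity = report$pattern_similarity[i],
             discrepancy_db = report$discrepancy_db[i],
             net_difference_db = report$net_difference_db[i],
             n_points = report$n_points[i])),
      paste0("layer_", report$layer)),
    file.path(out_dir, "similarity.json"), auto_unbox = TRUE, digits = NA)

  # stage 5: neurophysiology ------------------------------------------------
  stage_msg(log_path, "neurophys", "measuring AM tuning")
  tuning_tbl <- dplyr::bind_rows(purrr::map(layers, function(li) {
    tu <- measure_tuning(layer_observer(model, li),
                         rates_hz = config$neurophys_rates,
                         sample_rate_hz = sr, duration_s = 0.5,
                         n_repeats = config$neurophys_repeats,
                         rng_seed = derive_seed(config$seed, 7L, li))
    dplyr::mutate(tu, layer = li)
  }))
  utils::write.csv(tuning_tbl, file.path(out_dir, "tuning.csv"),
                   row.names = FALSE)
  chars <- tuning_tbl |>
    dplyr::group_by(.data$layer) |>
    dplyr::group_modify(function(d, key) tuning_characteristics(d)) |>
    dplyr::ungroup()
  utils::write.csv(chars, file.path(out_dir, "characteristics.csv"),
                   row.names = FALSE)
  region_ref <- if (identical(config$reference_regions, "synthetic")) {
    synthetic_region_reference()
  } else {
    read_region_reference(config$reference_regions)
  }
  region_sim <- tryCatch(layer_region_map(chars, region_ref),
                         error = function(e) {
                           stage_msg(log_path, "neurophys",
                                     paste("no region map:", conditionMessage(e)))
                           NULL
                         })
  if (!is.null(region_sim)) {
    jsonlite::write_json(
      purrr::set_names(
        purrr::map(split(region_sim, region_sim$layer), function(d)
          purrr::set_names(as.list(d$similarity), d$region)),
        paste0("layer_", unique(region_sim$layer))),
      file.path(out_dir, "region_similarity.json"),
      auto_unbox = TRUE, digits = NA)
  }
  stage_msg(log_path, "done", "all artifacts written")
  res <- list(corpus = corpus, model = model, validation_accuracy = val_acc,
              tmtf = tmtf_tbl, psychometric = psy_tbl, similarity = report,
              tuning = tuning_tbl, characteristics = chars,
              region_similarity = region_sim)
  out <- out_dir
  attr(out, "results") <- res
  invisible(out)
}
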