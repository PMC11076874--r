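# End-to-end pipeline driver: simulate -> preprocess -> windows -> train ->
# evaluate -> transfer, with per-stage artifacts, resolved configs and a
# checksum manifest. Each stage consumes the previous stage's outputs from
# `out_dir`, so stages can be re-run selectively.

#' Default pipeline configuration
#'
#' Nested sections mirror the stage configurations. Override any entry by
#' passing a partial list to [run_pipeline()]; unspecified entries keep
#' these defaults.
#'
#' @param seed global seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(n_subjects = 4L, record_duration_s = 300,
                     fs_hz = 1024, spindle_rate_per_min = 3,
                     regime = "normal"),
    transfer_generator = list(n_subjects = 4L, record_duration_s = 300,
                              fs_hz = 1024, spindle_rate_per_min = 3,
                              regime = "insomnia"),
    preprocess = list(target_fs_hz = 100, band_hz = c(0.3, 30)),
    windowing = list(window_s = 3, guard_s = 0.5),
    model = list(),   # cnn_spec() overrides
    train = list(epochs = 5, batch_size = 128, lr0 = 0.003,
                 lr_decay_factor = 0.75, lr_decay_every = 3,
                 weight_decay = 0.01),
    evaluate = list(k = 4, grouping = "by_subject"),
    transfer = list(modes = c("all_conv", "first_four"),
                    freeze_transferred = TRUE, k = 4)
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  utils::modifyList(base, override)
}

pipeline_cohort <- function(gen_cfg, pre_cfg, seed) {
  cfg <- generator_config(
    fs_hz = gen_cfg$fs_hz, record_duration_s = gen_cfg$record_duration_s,
    spindle_rate_per_min = gen_cfg$spindle_rate_per_min,
    regime = spindle_regime(gen_cfg$regime), seed = seed)
  cohort <- simulate_cohort(gen_cfg$n_subjects, cfg,
                            id_prefix = if (gen_cfg$regime == "insomnia")
                              "I" else "S")
  pp <- preprocess_config(target_fs_hz = pre_cfg$target_fs_hz,
                          band_hz = pre_cfg$band_hz)
  lapply(cohort, function(s) {
    s$recording <- preprocess_recording(s$recording, pp)
    s
  })
}

#' Run the spindle classification pipeline
#'
#' Stages: `"simulate"` (synthetic source + target cohorts, preprocessed),
#' `"windows"` (balanced window sets), `"train"` (fit the CNN on the source
#' windows), `"evaluate"` (cross-validated metrics on the source windows),
#' `"transfer"` (transfer modes on the target windows). Every stage writes
#' its artifacts and resolved configuration under `out_dir` and appends to
#' a `manifest.csv` of MD5 checksums. Completed stages are skipped unless
#' `force = TRUE`; a stage whose inputs are missing names the stage to run
#' first.
#'
#' @param config partial configuration merged over [pipeline_config()].
#' @param stages which stages to run, in pipeline order.
#' @param out_dir artifact directory (created if needed).
#' @param force re-run stages whose outputs already exist.
#' @param verbose print stage progress.
#' @return invisibly, a list with the artifacts of the executed stages.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "windows", "train",
                                    "evaluate", "transfer"),
                         out_dir = "spindlecnn-run", force = FALSE,
                         verbose = TRUE) {
  cfg <- merge_config(pipeline_config(), config)
  if (cfg$preprocess$band_hz[1] >= cfg$preprocess$band_hz[2]) {
    stopf("invalid band edges (%g, %g): low must be below high",
          cfg$preprocess$band_hz[1], cfg$preprocess$band_hz[2])
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(out_dir, name)
  note <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  results <- list()

  need <- function(name, producer) {
    if (!file.exists(art(name))) {
      stopf("missing artifact '%s'; run stage '%s' first", name, producer)
    }
    readRDS(art(name))
  }
  emit <- function(obj, name) {
    saveRDS(obj, art(name))
    obj
  }

  if ("simulate" %in% stages &&
      (force || !file.exists(art("cohorts.rds")))) {
    note("[simulate] generating source and target cohorts")
    cohorts <- list(
      source = pipeline_cohort(cfg$generator, cfg$preprocess,
                               derive_seed(cfg$seed, "source-cohort")),
      target = pipeline_cohort(cfg$transfer_generator, cfg$preprocess,
                               derive_seed(cfg$seed, "target-cohort")))
    results$cohorts <- emit(cohorts, "cohorts.rds")
  }

  if ("windows" %in% stages &&
      (force || !file.exists(art("windows.rds")))) {
    cohorts <- results$cohorts %||% need("cohorts.rds", "simulate")
    note("[windows] building balanced window sets")
    windows <- lapply(cohorts, function(coh) {
      build_window_set(coh, window_s = cfg$windowing$window_s,
                       guard_s = cfg$windowing$guard_s,
                       seed = derive_seed(cfg$seed, "windows"))
    })
    results$windows <- emit(windows, "windows.rds")
  }

  if ("train" %in% stages && (force || !file.exists(art("model.rds")))) {
    windows <- results$windows %||% need("windows.rds", "windows")
    note("[train] fitting the CNN on source windows")
    fit <- do.call(spindle_cnn, c(
      list(windows$source, spec = do.call(cnn_spec, cfg$model),
           seed = derive_seed(cfg$seed, "train")),
      cfg$train))
    results$model <- fit
    save_spindle_cnn(fit, art("model.rds"))
  }

  if ("evaluate" %in% stages &&
      (force || !file.exists(art("eval_report.csv")))) {
    windows <- results$windows %||% need("windows.rds", "windows")
    note("[evaluate] %d-fold cross-validation on source windows",
         cfg$evaluate$k)
    cv <- do.call(cross_validate, c(
      list(windows$source, spec = do.call(cnn_spec, cfg$model),
           k = cfg$evaluate$k, grouping = cfg$evaluate$grouping,
           seed = derive_seed(cfg$seed, "evaluate")),
      cfg$train))
    results$evaluation <- cv
    emit(cv, "evaluation.rds")
    tab <- cv$per_fold
    tab <- rbind(tab, data.frame(fold = NA, t(cv$mean)))
    utils::write.csv(tab, art("eval_report.csv"), row.names = FALSE)
  }

  if ("transfer" %in% stages &&
      (force || !file.exists(art("transfer_report.rds")))) {
    windows <- results$windows %||% need("windows.rds", "windows")
    note("[transfer] evaluating transfer modes on target windows")
    tr <- transfer_experiment(
      windows$source, windows$target,
      spec = do.call(cnn_spec, cfg$model),
      modes = cfg$transfer$modes, k = cfg$transfer$k,
      freeze_transferred = cfg$transfer$freeze_transferred,
      seed = derive_seed(cfg$seed, "transfer"),
      source_args = cfg$train, finetune_args = cfg$train)
    results$transfer <- emit(tr, "transfer_report.rds")
  }

  saveRDS(cfg, art("resolved_config.rds"))
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, art("manifest.csv"), row.names = FALSE)
  invisible(results)
}
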