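#' Run the full aging-clock pipeline
#'
#' Executes the stages in order: simulate (or read input) -> QC filter ->
#' pseudocell aggregation + normalization -> leave-pair-out
#' cross-validation on the vehicle samples -> full-vehicle clock training
#' per cell type -> prediction of every sample (including the treated
#' group) -> rejuvenation testing -> driver-gene summary. Every stage
#' derives its seed from the root seed via [stage_seed()], so a rerun with
#' the same config reproduces all numeric outputs; stage parameters and
#' seeds are logged to a JSON run manifest.
#'
#' @param config A [pipeline_config()] (or a list coercible to one).
#' @param out_dir Output directory; created if needed. When `NULL`,
#'   nothing is written and results are only returned.
#' @param quiet Suppress progress messages.
#' @return A list with `bundle`, `qc`, `pseudocells`, `cv`, `models`,
#'   `predictions` (pseudocell-level data frame), `rejuvenation`,
#'   `drivers`, `truth` (when simulated), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  say <- function(...) if (!quiet) message("[cellclock] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("cellclock")),
                   r_version = R.version.string,
                   seed = config$seed,
                   stages = list())
  note_stage <- function(name, params) {
    manifest$stages[[name]] <<- c(list(seed = stage_seed(config$seed, name)),
                                  params)
  }

  ## stage: simulate or read
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- stage_seed(config$seed, "simulate")
    sim_cfg <- tryCatch(do.call(simulation_config, sim_args),
                        error = function(e) abort_ctx("simulate",
                                                      conditionMessage(e)))
    say("simulating dataset (", sim_cfg$n_genes, " genes, ",
        sim_cfg$n_cell_types, " cell types)")
    sim <- tryCatch(simulate_dataset(sim_cfg),
                    error = function(e) abort_ctx("simulate",
                                                  conditionMessage(e)))
    bundle <- sim$bundle
    truth <- sim$truth
    note_stage("simulate", sim_cfg[setdiff(names(sim_cfg), "aging_genes")])
  } else {
    say("reading bundle from ", config$input_path)
    bundle <- tryCatch(read_bundle(config$input_path),
                       error = function(e) abort_ctx("read",
                                                     conditionMessage(e)))
    note_stage("read", list(input_path = config$input_path))
  }

  ## stage: qc
  qc <- NULL
  if (isTRUE(config$qc$enabled)) {
    say("QC filtering (", config$qc$n_sd, "-SD band)")
    qc <- tryCatch(qc_filter_bundle(bundle, n_sd = config$qc$n_sd),
                   error = function(e) abort_ctx("qc", conditionMessage(e)))
    bundle <- qc$bundle
    note_stage("qc", list(n_sd = config$qc$n_sd,
                          n_removed = length(qc$removed_barcodes)))
  }

  ## stage: pseudocell
  say("building pseudocells")
  pc <- config$pseudocell
  pset <- tryCatch(
    make_pseudocells(bundle,
                     cells_per_pseudocell = pc$cells_per_pseudocell,
                     n_reps = pc$n_reps,
                     min_cells_per_stratum = pc$min_cells_per_stratum,
                     seed = stage_seed(config$seed, "pseudocell")),
    error = function(e) abort_ctx("pseudocell", conditionMessage(e)))
  pset <- normalize_pseudocells(pset, scale = pc$scale)
  note_stage("pseudocell", pc)

  samples <- unique(bundle$cell_metadata[, c("sample", "group")])
  young_ids <- samples$sample[samples$group == "young_vehicle"]
  aged_ids <- samples$sample[samples$group == "aged_vehicle"]
  ck <- config$clock

  ## stage: cv
  cv <- NULL
  if (isTRUE(config$cv$enabled)) {
    say("leave-pair-out cross-validation (", length(young_ids), "+",
        length(aged_ids), " vehicle samples)")
    folds <- tryCatch(
      build_pair_folds(young_ids, aged_ids,
                       seed = stage_seed(config$seed, "cv_folds")),
      error = function(e) abort_ctx("cv", conditionMessage(e)))
    cv <- tryCatch(
      run_cv(pset, folds, alpha = ck$alpha,
             inner_cv_folds = ck$inner_cv_folds,
             min_detect_frac = ck$min_detect_frac,
             seed = stage_seed(config$seed, "cv")),
      error = function(e) abort_ctx("cv", conditionMessage(e)))
    note_stage("cv", c(ck, list(n_folds = length(folds))))
  }

  ## stage: train full-vehicle clocks and predict everyone
  say("training full-vehicle clocks")
  vehicle_idx <- pset$labels$group %in% c("young_vehicle", "aged_vehicle")
  cell_types <- sort(unique(pset$labels$cell_type))
  models <- list()
  predictions <- list()
  for (ct in cell_types) {
    train_pset <- subset_pseudocells(pset, vehicle_idx &
                                       pset$labels$cell_type == ct)
    models[[ct]] <- tryCatch(
      train_clock(train_pset, cell_type = ct, alpha = ck$alpha,
                  inner_cv_folds = ck$inner_cv_folds,
                  min_detect_frac = ck$min_detect_frac,
                  seed = stage_seed(config$seed, paste0("train.", ct))),
      error = function(e) abort_ctx("train", paste0(ct, ": ",
                                                    conditionMessage(e))))
    pred <- predict_age(models[[ct]],
                        subset_pseudocells(pset,
                                           pset$labels$cell_type == ct))
    predictions[[ct]] <- pred$predictions
  }
  predictions <- do.call(rbind, c(predictions, list(make.row.names = FALSE)))
  note_stage("train", ck)

  ## stage: rejuvenation
  say("rejuvenation testing")
  rejuvenation <- tryCatch(assess_rejuvenation(predictions),
                           error = function(e) abort_ctx("rejuvenation",
                                                         conditionMessage(e)))
  flags <- stats::setNames(rejuvenation$summary$significant_rejuvenation,
                           rejuvenation$summary$cell_type)
  note_stage("rejuvenation", list(alpha = rejuvenation$alpha))

  ## stage: drivers
  say("driver-gene summary")
  drivers <- summarize_drivers(models, rejuvenation_flags = flags,
                               k_values = config$k_values)
  note_stage("drivers", list(k_values = config$k_values,
                             n_flagged = sum(flags)))

  result <- list(bundle = bundle, qc = qc, pseudocells = pset, cv = cv,
                 models = models, predictions = predictions,
                 rejuvenation = rejuvenation, drivers = drivers,
                 truth = truth, manifest = manifest, config = config)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$qc)) {
    wt(result$qc$report, "qc_report.tsv")
    jsonlite::write_json(
      list(n_removed = length(result$qc$removed_barcodes),
           removed_barcodes = result$qc$removed_barcodes),
      file.path(out_dir, "qc_summary.json"), auto_unbox = TRUE)
  }
  write_pseudocells(result$pseudocells, file.path(out_dir, "pseudocells"))
  if (!is.null(result$cv)) {
    wt(result$cv$summary, "cv_result.tsv")
    jsonlite::write_json(
      list(summary = result$cv$summary,
           folds = lapply(result$cv$folds, function(f) f[c("test", "train")])),
      file.path(out_dir, "cv_result.json"), auto_unbox = TRUE, digits = NA)
  }
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  for (ct in names(result$models)) {
    write_clock_model(result$models[[ct]],
                      file.path(out_dir, "models", paste0(ct, ".json")))
  }
  # heatmap-ready long table: sample x cell type x mean predicted age
  wt(result$predictions, "predictions.tsv")
  long <- stats::aggregate(predicted_age ~ sample + group + cell_type,
                           data = result$predictions, FUN = mean)
  names(long)[names(long) == "predicted_age"] <- "mean_predicted_age"
  wt(long, "predicted_age_by_sample.tsv")
  wt(result$rejuvenation$summary, "rejuvenation_result.tsv")
  jsonlite::write_json(result$rejuvenation$summary,
                       file.path(out_dir, "rejuvenation_result.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(gene_sets = result$drivers$gene_sets,
         shared = result$drivers$shared,
         counts = result$drivers$counts),
    file.path(out_dir, "drivers.json"), auto_unbox = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
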