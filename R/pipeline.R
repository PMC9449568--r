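#' Configuration of a full pipeline run
#'
#' Collects every tunable of the end-to-end analysis. With `world = NULL`
#' the pipeline reads rasters and occurrences from `paths`; with a
#' [world_config()] it simulates the virtual-species world instead, so the
#' whole analysis runs without external data. Every stochastic stage draws
#' its seed from `seed`, making a run reproducible from the one number.
#'
#' @param world a [world_config()] for a simulated run, or `NULL`.
#' @param species a [virtual_species()] (simulated runs).
#' @param n_presences presence points sampled from the true suitability
#'   (simulated runs).
#' @param paths named list for data-driven runs: `rasters` (named vector of
#'   `.asc` paths), `occurrences` (CSV path), `scenario_rasters` (named list
#'   of named vectors, one per scenario).
#' @param sampling a [sampling_config()] for pseudo-absence generation.
#' @param r_threshold,vif_threshold collinearity screen thresholds.
#' @param k,runs cross-validation folds and repeats.
#' @param scheme a [suitability_scheme()].
#' @param scenarios named list of [scenario_shift()] objects (simulated
#'   runs).
#' @param weighting_metric ensemble weighting metric.
#' @param seed master seed.
#' @param outdir output directory (created if missing).
#' @return an object of class `run_config`.
#' @export
run_config <- function(world = world_config(seed = seed),
                       species = virtual_species(),
                       n_presences = 400L,
                       paths = NULL,
                       sampling = sampling_config(n_pseudo_absence = 800,
                                                  min_distance_km = 5),
                       r_threshold = 0.7, vif_threshold = 10,
                       k = 4L, runs = 10L,
                       scheme = suitability_scheme(),
                       scenarios = list(
                         "2050 RCP4.5" = scenario_shift(
                           c(sig1 = 0.5, sig2 = 0.25), "2050 RCP4.5"),
                         "2070 RCP8.5" = scenario_shift(
                           c(sig1 = 1, sig2 = 0.5), "2070 RCP8.5")),
                       weighting_metric = "AUC",
                       seed = 1L, outdir = tempfile("sdm_run_")) {
  structure(list(world = world, species = species,
                 n_presences = as.integer(n_presences), paths = paths,
                 sampling = sampling, r_threshold = r_threshold,
                 vif_threshold = vif_threshold, k = as.integer(k),
                 runs = as.integer(runs), scheme = scheme,
                 scenarios = scenarios,
                 weighting_metric = weighting_metric,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

pipeline_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full ensemble SDM pipeline
#'
#' Executes prepare (dedup + pseudo-absences), predictor screening,
#' repeated stratified cross-validation of the five learners, skill-weighted
#' ensemble fitting, current and per-scenario suitability prediction,
#' four-class classification with area accounting, change mapping and
#' change-rate reporting. All tables, rasters and a JSON manifest (config
#' echo, seeds, per-stage counts, file checksums) are written to
#' `config$outdir`; the key objects are also returned invisibly.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the fitted ensemble, performance and
#'   importance tables, per-scenario summaries, the scenario report and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logfile))
  counts <- list()

  # --- inputs: simulate or load ------------------------------------------
  if (!is.null(config$world)) {
    pipeline_log(logfile, "simulate: building synthetic world")
    stack <- make_climate_stack(config$world)
    truth <- true_suitability(config$species, stack)
    presences <- sample_presences(truth, config$n_presences,
                                  seed = derive_seeds(config$seed, 1, 11L))
    scen_stacks <- lapply(config$scenarios, function(s) apply_shift(stack, s))
  } else {
    if (is.null(config$paths)) stop("either `world` or `paths` is required")
    pipeline_log(logfile, "load: reading rasters and occurrences")
    rl <- lapply(config$paths$rasters, read_raster)
    stack <- align_stack(rl, names(config$paths$rasters))
    presences <- read_occurrences(config$paths$occurrences)
    truth <- NULL
    scen_stacks <- lapply(config$paths$scenario_rasters, function(ps) {
      align_stack(lapply(ps, read_raster), names(ps))
    })
  }

  # --- prepare ------------------------------------------------------------
  presences <- deduplicate(presences, stack)
  counts$presences <- nrow(presences)
  cfg_s <- config$sampling
  cfg_s$seed <- derive_seeds(config$seed, 1, 13L)
  absences <- generate_pseudo_absences(presences, stack, cfg_s)
  counts$pseudo_absences <- nrow(absences)
  occ <- rbind(as.data.frame(presences), as.data.frame(absences))
  occ <- occurrence_set(occ$lon, occ$lat, occ$label, occ$source)
  write_occurrences(occ, file.path(config$outdir, "occurrences.csv"))
  pipeline_log(logfile, "prepare: ", counts$presences, " presences + ",
               counts$pseudo_absences, " pseudo-absences")

  # --- screen -------------------------------------------------------------
  features <- extract_features(stack, occ)
  screen <- screen_predictors(features, config$r_threshold,
                              config$vif_threshold)
  kept <- features[, c(screen$retained, "label"), drop = FALSE]
  class(kept) <- class(features)
  counts$predictors_in <- length(feature_columns(features))
  counts$predictors_kept <- length(screen$retained)
  jsonlite::write_json(
    list(retained = screen$retained,
         dropped_by_correlation = screen$dropped_by_correlation,
         dropped_by_vif = screen$dropped_by_vif,
         r_threshold = screen$r_threshold,
         vif_threshold = screen$vif_threshold),
    file.path(config$outdir, "screen_report.json"),
    auto_unbox = TRUE, digits = NA)
  pipeline_log(logfile, "select-vars: kept ", counts$predictors_kept, " of ",
               counts$predictors_in, " predictors (",
               paste(screen$retained, collapse = ", "), ")")

  # --- evaluate -----------------------------------------------------------
  specs <- default_algorithm_specs(derive_seeds(config$seed, 1, 17L))
  cv <- cross_validate(kept, specs, k = config$k, runs = config$runs,
                       seed = derive_seeds(config$seed, 1, 19L))
  replicates <- evaluate_cv(cv)
  perf <- performance_table(replicates)
  utils::write.csv(perf, file.path(config$outdir, "performance_table.csv"),
                   row.names = FALSE)
  pipeline_log(logfile, "evaluate: mean AUC ",
               sprintf("%.2f", perf$auc[nrow(perf)]), ", mean TSS ",
               sprintf("%.2f", perf$tss[nrow(perf)]))

  # --- fit final members + ensemble --------------------------------------
  members <- lapply(specs, fit_model, table = kept)
  member_eval <- perf[match(vapply(members, function(m) m$spec$algorithm_id,
                                   character(1)), perf$algorithm), ]
  ensemble <- build_ensemble(members, member_eval, config$weighting_metric)
  importance <- variable_importance(ensemble, kept,
                                    seed = derive_seeds(config$seed, 1, 29L))
  utils::write.csv(importance,
                   file.path(config$outdir, "variable_importance.csv"),
                   row.names = FALSE)

  # --- predict + classify current and scenarios --------------------------
  predict_and_classify <- function(stk, tag) {
    suit <- ensemble_predict_raster(ensemble, stk)
    write_raster(suit, file.path(config$outdir,
                                 paste0("suitability_", gsub("[^A-Za-z0-9.]+",
                                                             "_", tag),
                                        ".asc")))
    cls <- classify_suitability(suit, config$scheme)
    list(suitability = suit, classes = cls,
         summary = area_summary(cls, tag, config$scheme))
  }
  cur <- predict_and_classify(stack, "current")
  futs <- lapply(names(scen_stacks), function(nm) {
    predict_and_classify(scen_stacks[[nm]], nm)
  })
  names(futs) <- names(scen_stacks)
  pipeline_log(logfile, "predict: 1 current + ", length(futs),
               " scenario suitability raster(s)")

  # --- change accounting --------------------------------------------------
  report <- scenario_report(cur$summary, lapply(futs, `[[`, "summary"))
  utils::write.csv(report$suitability,
                   file.path(config$outdir, "suitability_by_scenario.csv"),
                   row.names = FALSE)
  utils::write.csv(report$change_rate,
                   file.path(config$outdir, "change_rate_by_scenario.csv"),
                   row.names = FALSE)
  changes <- lapply(futs, function(f) {
    change_map(cur$classes, f$classes, scheme = config$scheme)
  })
  change_counts <- do.call(rbind, lapply(names(changes), function(nm) {
    data.frame(scenario = nm, t(attr(changes[[nm]], "counts")),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(change_counts,
                   file.path(config$outdir, "change_category_counts.csv"),
                   row.names = FALSE)
  pipeline_log(logfile, "change: accounted ", length(changes), " scenario(s)")

  # --- manifest -----------------------------------------------------------
  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|run\\.log$", files)]
  manifest <- list(
    seed = config$seed,
    weighting_metric = config$weighting_metric,
    r_threshold = config$r_threshold,
    vif_threshold = config$vif_threshold,
    cv = list(k = config$k, runs = config$runs),
    classification_convention = config$scheme$convention,
    counts = counts,
    n_scenarios = length(scen_stacks),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(ensemble = ensemble, performance = perf,
                 cv = cv, replicates = replicates, importance = importance,
                 screen = screen, features = kept,
                 truth = truth, stack = stack, scenario_stacks = scen_stacks,
                 current = cur, futures = futs, report = report,
                 changes = changes, manifest = manifest,
                 outdir = config$outdir))
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a plain-text config and resolves it against the [run_config()]
#' defaults, so a file needs to state only what it overrides. Recognised
#' top-level keys: `seed`, `outdir`, `n_presences`, `r_threshold`,
#' `vif_threshold`, `k`, `runs`, `weighting_metric`, `world` (fields of
#' [world_config()]), `sampling` (fields of [sampling_config()]), and
#' `scenarios` (name -> named delta map).
#'
#' @param path path to a YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("seed", "outdir", "n_presences", "r_threshold",
                "vif_threshold", "k", "runs", "weighting_metric")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$world)) args$world <- do.call(world_config, y$world)
  if (!is.null(y$sampling)) args$sampling <- do.call(sampling_config,
                                                     y$sampling)
  if (!is.null(y$scenarios)) {
    args$scenarios <- lapply(stats::setNames(names(y$scenarios),
                                             names(y$scenarios)),
                             function(nm) {
                               scenario_shift(unlist(y$scenarios[[nm]]), nm)
                             })
  }
  do.call(run_config, args)
}
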