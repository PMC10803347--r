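#' End-to-end run configuration
#'
#' Bundles every stage's configuration for [run_pipeline()]: the generator,
#' the SOFA windows, onset definitions, horizons, exclusion variant,
#' feature spec, model kinds and the global seed. Per-stage seeds are
#' derived deterministically from the global seed so stage-local reruns are
#' stable.
#'
#' @param generator A [cohort_config()].
#' @param windows List of [sofa_window()]s.
#' @param definitions,models,horizons,variant Experiment axes.
#' @param feature_spec A [feature_spec()].
#' @param exclusions An [exclusion_config()].
#' @param n_resamples Bootstrap resamples.
#' @param seed Global seed.
#' @return A list of class `slab_run_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            windows = list(sofa_window(24, 12)),
                            definitions = c("H1", "H2", "H3"),
                            models = "gbm",
                            horizons = 6,
                            variant = "main",
                            feature_spec = default_feature_spec(),
                            exclusions = exclusion_config(),
                            n_resamples = 100,
                            seed = 1L) {
  structure(list(generator = generator, windows = windows,
                 definitions = definitions, models = models,
                 horizons = horizons, variant = variant,
                 feature_spec = feature_spec, exclusions = exclusions,
                 n_resamples = n_resamples, seed = as.integer(seed)),
            class = "slab_run_config")
}

# semantic content hash: JSON serialisation ignores volatile attributes
# (e.g. data.table's lazily added secondary indices)
config_hash <- function(x) {
  md5_of(as.character(jsonlite::toJSON(x, force = TRUE, auto_unbox = TRUE,
                                       digits = NA, null = "null")))
}

stage_cached <- function(stage_dir, hash) {
  mf <- file.path(stage_dir, "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  m <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  !is.null(m) && identical(m$hash, hash)
}

write_stage_manifest <- function(stage_dir, stage, hash, seed, inputs = NULL) {
  jsonlite::write_json(list(stage = stage, hash = hash, seed = seed,
                            inputs = inputs,
                            nonce = sprintf("%08x-%s",
                                            sample.int(.Machine$integer.max, 1),
                                            format(Sys.time(), "%Y%m%d%H%M%S")),
                            written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
}

# identity of a stage's current outputs: config hash + recompute nonce, so
# downstream caches are invalidated whenever an upstream stage was rebuilt
stage_token <- function(stage_dir) {
  mf <- file.path(stage_dir, "manifest.json")
  if (!file.exists(mf)) return("missing")
  m <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  if (is.null(m)) "unreadable" else paste0(m$hash, "/", m$nonce %||% "")
}

#' Run the full pipeline with per-stage caching
#'
#' Executes generate, sofa, suspicion, label, featurize and evaluate in
#' order, writing each stage's artifacts and a manifest (stage config hash
#' and seed) under `out_dir`. A stage whose manifest hash matches the
#' current configuration -- which incorporates the hashes of its upstream
#' stages -- is skipped unless `force`; deleting an intermediate stage
#' directory therefore recomputes only that stage and everything downstream.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory.
#' @param force Recompute every stage.
#' @param verbose Log stage progress to stderr.
#' @return The `slab_experiment` result of the evaluate stage (invisibly
#'   also written as JSON/CSV under `out_dir/evaluate`).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, verbose = TRUE) {
  if (!inherits(config, "slab_run_config"))
    stopf("config must be created by pipeline_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) if (verbose) message(sprintf(...))
  t_stage <- function(nm, expr) {
    t0 <- Sys.time()
    r <- expr
    msg("stage %-10s %6.1f s", nm,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    r
  }

  # ---- generate ----------------------------------------------------------
  gen_dir <- file.path(out_dir, "generate")
  gen_hash <- config_hash(config$generator)
  if (force || !stage_cached(gen_dir, gen_hash)) {
    cohort <- t_stage("generate", generate_cohort(config$generator))
    write_cohort(cohort, gen_dir)
    write_stage_manifest(gen_dir, "generate", gen_hash, config$generator$seed)
  } else {
    msg("stage generate   cached")
    cohort <- read_cohort(gen_dir)
  }

  # ---- sofa --------------------------------------------------------------
  sofa_dir <- file.path(out_dir, "sofa")
  sofa_hash <- config_hash(list(upstream = stage_token(gen_dir)))
  if (force || !stage_cached(sofa_dir, sofa_hash)) {
    dir.create(sofa_dir, showWarnings = FALSE)
    sofa <- t_stage("sofa", {
      grid <- build_hourly_grid(cohort$observations, cohort$stays)
      compute_sofa(grid)
    })
    data.table::fwrite(sofa, file.path(sofa_dir, "sofa.csv"))
    write_stage_manifest(sofa_dir, "sofa", sofa_hash, config$seed,
                         inputs = gen_hash)
  } else {
    msg("stage sofa       cached")
    sofa <- data.table::fread(file.path(sofa_dir, "sofa.csv"))
  }

  # ---- suspicion ---------------------------------------------------------
  susp_dir <- file.path(out_dir, "suspicion")
  susp_hash <- config_hash(list(upstream = stage_token(gen_dir),
                                other = config$variant == "other_cultures"))
  if (force || !stage_cached(susp_dir, susp_hash)) {
    dir.create(susp_dir, showWarnings = FALSE)
    susp <- t_stage("suspicion", compute_suspicion(
      cohort$dose_events, cohort$culture_events, cohort$stays,
      include_other_specimens = config$variant == "other_cultures"))
    data.table::fwrite(susp$episodes, file.path(susp_dir, "episodes.csv"))
    data.table::fwrite(susp$suspicion, file.path(susp_dir, "suspicion.csv"))
    write_stage_manifest(susp_dir, "suspicion", susp_hash, config$seed,
                         inputs = gen_hash)
  } else {
    msg("stage suspicion  cached")
  }

  # ---- label -------------------------------------------------------------
  lab_dir <- file.path(out_dir, "label")
  lab_hash <- config_hash(list(upstream = c(stage_token(gen_dir),
                                            stage_token(sofa_dir),
                                            stage_token(susp_dir)),
                               windows = config$windows,
                               exclusions = config$exclusions,
                               variant = config$variant))
  if (force || !stage_cached(lab_dir, lab_hash)) {
    dir.create(lab_dir, showWarnings = FALSE)
    t_stage("label", {
      flow <- list()
      for (w in config$windows) {
        onsets <- label_onsets(cohort$stays, cohort$observations,
                               cohort$dose_events, cohort$culture_events,
                               window = w, sofa = sofa,
                               include_other_specimens =
                                 config$variant == "other_cultures")
        wtag <- sprintf("w%g_%g", w$x, w$y)
        data.table::fwrite(onsets, file.path(lab_dir,
                                             paste0("onsets_", wtag, ".csv")))
        for (def in config$definitions) {
          cfg <- config$exclusions
          cfg$strict_h3_grace <- config$variant == "strict"
          asm <- apply_exclusions(cohort$stays, onsets, cohort$observations,
                                  cfg, def)
          flow[[paste(wtag, def, sep = "_")]] <- attr(asm, "flow")
          data.table::fwrite(asm, file.path(lab_dir,
            paste0("assembly_", wtag, "_", def, ".csv")))
        }
      }
      jsonlite::write_json(flow, file.path(lab_dir, "flow_report.json"),
                           auto_unbox = TRUE)
    })
    write_stage_manifest(lab_dir, "label", lab_hash, config$seed)
  } else msg("stage label      cached")

  # ---- featurize ---------------------------------------------------------
  feat_dir <- file.path(out_dir, "featurize")
  feat_hash <- config_hash(list(upstream = stage_token(gen_dir),
                                spec = config$feature_spec))
  if (force || !stage_cached(feat_dir, feat_hash)) {
    dir.create(feat_dir, showWarnings = FALSE)
    features <- t_stage("featurize", {
      grid <- build_hourly_grid(cohort$observations, cohort$stays)
      assemble_matrix(grid, config$feature_spec, cohort$stays,
                      cohort$observations)
    })
    data.table::fwrite(features, file.path(feat_dir, "features.csv"))
    jsonlite::write_json(feature_names(config$feature_spec),
                         file.path(feat_dir, "schema.json"))
    write_stage_manifest(feat_dir, "featurize", feat_hash, config$seed)
  } else {
    msg("stage featurize  cached")
    features <- data.table::fread(file.path(feat_dir, "features.csv"))
  }

  # ---- evaluate ----------------------------------------------------------
  eval_dir <- file.path(out_dir, "evaluate")
  eval_hash <- config_hash(list(upstream = c(stage_token(lab_dir),
                                             stage_token(feat_dir)),
                                models = config$models,
                                horizons = config$horizons,
                                n_resamples = config$n_resamples,
                                seed = config$seed))
  if (force || !stage_cached(eval_dir, eval_hash)) {
    dir.create(eval_dir, showWarnings = FALSE)
    result <- t_stage("evaluate", run_experiment(
      cohort,
      definitions = config$definitions, models = config$models,
      windows = config$windows, horizons = config$horizons,
      variants = config$variant, feature_spec = config$feature_spec,
      exclusions = config$exclusions, n_resamples = config$n_resamples,
      seed = config$seed, features = features, verbose = verbose))
    data.table::fwrite(result$reports, file.path(eval_dir, "reports.csv"))
    jsonlite::write_json(list(reports = result$reports,
                              comparison_note = result$comparison_note,
                              skipped = result$skipped),
                         file.path(eval_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_stage_manifest(eval_dir, "evaluate", eval_hash, config$seed)
    saveRDS(result, file.path(eval_dir, "experiment.rds"))
  } else {
    msg("stage evaluate   cached")
    result <- readRDS(file.path(eval_dir, "experiment.rds"))
  }
  result
}
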