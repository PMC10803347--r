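#' Run the definition-sensitivity experiment grid
#'
#' Executes the full evaluation protocol on a cohort: a stratified
#' train/test split assigned before exclusions, then for every combination
#' of SOFA window, exclusion variant, onset definition and model kind --
#' onset labeling, exclusions, hourly labels for the horizon, model fitting
#' on training patients' pre-onset hours, threshold calibration to the
#' target training sensitivity, and test-set patient-hour AUROC with a
#' patient-level bootstrap confidence interval plus sensitivity,
#' specificity and accuracy at the calibrated threshold.
#'
#' Exclusion variants: `"main"` (each definition's own exclusions),
#' `"strict"` (H1/H2 cohorts additionally drop every stay H3 would drop for
#' early onset; identical to main for H3), `"other_cultures"` (non-blood
#' specimens also count in the suspicion pairing).
#'
#' @param cohort A `slab_cohort` (or any list with the same five tables).
#' @param definitions Subset of `c("H1", "H2", "H3")`.
#' @param models Subset of `c("gbm", "lstm", "coxphm")`.
#' @param windows List of [sofa_window()]s (or `c(x, y)` vectors).
#' @param horizons Prediction horizons in hours.
#' @param variants Subset of `c("main", "strict", "other_cultures")`.
#' @param feature_spec A [feature_spec()].
#' @param exclusions An [exclusion_config()] (variant flags are applied on
#'   top of it).
#' @param train_fraction,split_seed Stratified split parameters.
#' @param n_resamples Bootstrap resamples for the AUROC interval.
#' @param target_sensitivity Training sensitivity target for the threshold.
#' @param model_params Optional named list (by kind) of hyperparameter
#'   overrides.
#' @param seed Global seed; per-model child seeds are derived from it.
#' @param features Optional precomputed feature matrix from
#'   [assemble_matrix()] (recomputed if `NULL`).
#' @param keep_roc Also return ROC point sets per cell.
#' @param verbose Print per-cell progress.
#' @return List of class `slab_experiment`: `reports` (one row per grid
#'   cell), `roc` (named list of ROC point sets), `comparison_note`,
#'   `split`, and the per-cell skip reasons.
#' @export
run_experiment <- function(cohort,
                           definitions = c("H1", "H2", "H3"),
                           models = c("gbm", "lstm", "coxphm"),
                           windows = list(sofa_window(24, 12)),
                           horizons = 6,
                           variants = "main",
                           feature_spec = default_feature_spec(),
                           exclusions = exclusion_config(),
                           train_fraction = 0.85,
                           split_seed = NULL,
                           n_resamples = 100,
                           target_sensitivity = 0.85,
                           model_params = list(),
                           seed = 1L,
                           features = NULL,
                           keep_roc = FALSE,
                           verbose = TRUE) {
  stopifnot(all(definitions %in% c("H1", "H2", "H3")),
            all(models %in% c("gbm", "lstm", "coxphm")),
            all(variants %in% c("main", "strict", "other_cultures")))
  if (!length(definitions) || !length(models) || !length(windows) ||
      !length(horizons) || !length(variants))
    stopf("experiment grid has an empty axis")
  windows <- lapply(windows, function(w)
    if (inherits(w, "slab_sofa_window")) w else sofa_window(w[1], w[2]))
  split_seed <- split_seed %||% child_seed(seed, "split")
  msg <- function(...) if (verbose) message(sprintf(...))

  stays <- data.table::as.data.table(cohort$stays)
  split <- split_train_test(stays, train_fraction, seed = split_seed)

  msg("building hourly grid and SOFA trace ...")
  grid <- build_hourly_grid(cohort$observations, stays)
  sofa <- compute_sofa(grid)
  if (is.null(features)) {
    msg("assembling feature matrix (%d columns) ...",
        length(feature_names(feature_spec)))
    features <- assemble_matrix(grid, feature_spec, stays, cohort$observations)
  }

  reports <- list(); roc <- list(); skipped <- list()
  for (w in windows) for (variant in variants) {
    onsets <- label_onsets(cohort$stays, cohort$observations,
                           cohort$dose_events, cohort$culture_events,
                           window = w,
                           include_other_specimens = variant == "other_cultures",
                           sofa = sofa)
    for (definition in definitions) {
      excl_cfg <- exclusions
      excl_cfg$strict_h3_grace <- variant == "strict"
      assembly <- apply_exclusions(stays, onsets, cohort$observations,
                                   excl_cfg, definition)
      kept <- stays[stay_id %in% assembly[included == TRUE, stay_id]]
      ons_col <- onsets[, .(stay_id,
                            t_sepsis = get(paste0("t_sepsis_", tolower(definition))))]
      for (T_h in horizons) {
        labels_T <- make_hourly_labels(kept, onsets, definition, horizon = T_h)
        sp <- merge(labels_T, split, by = "stay_id")
        tr_rows <- sp[split == "train"]; te_rows <- sp[split == "test"]
        cell_base <- sprintf("%s|w{%g,%g}|T%g|%s", definition, w$x, w$y,
                             T_h, variant)
        if (sum(tr_rows$label) == 0L || sum(te_rows$label) == 0L ||
            all(te_rows$label == 1L)) {
          skipped[[cell_base]] <- "a split side lacks both label classes"
          next
        }
        feat_tr <- merge(features, tr_rows[, .(stay_id, hour)],
                         by = c("stay_id", "hour"))
        feat_te <- merge(features, te_rows[, .(stay_id, hour)],
                         by = c("stay_id", "hour"))
        for (kind in models) {
          cell <- paste0(kind, "|", cell_base)
          msg("fitting %s ...", cell)
          pars <- model_params[[kind]] %||% list()
          scorer <- fit_risk_model(kind, feat_tr, tr_rows, horizon = T_h,
                                   onsets = ons_col, params = pars,
                                   seed = child_seed(seed, cell))
          d_tr <- merge_features_labels(feat_tr, tr_rows)
          d_te <- merge_features_labels(feat_te, te_rows)
          s_tr <- predict(scorer, d_tr)
          s_te <- predict(scorer, d_te)
          thr <- calibrate_threshold(s_tr, d_tr$label, target_sensitivity)
          au <- auroc(s_te, d_te$label)
          ci <- bootstrap_ci(auroc, s_te, d_te$label, d_te$stay_id,
                             n_resamples = n_resamples,
                             seed = child_seed(seed, paste0("boot|", cell)))
          cm <- confusion_metrics(s_te >= thr$threshold, d_te$label)
          reports[[cell]] <- data.table(
            definition = definition, model = kind, window_x = w$x,
            window_y = w$y, horizon = T_h, variant = variant,
            auroc = au, auroc_lower = ci[1], auroc_upper = ci[2],
            sensitivity = cm[["sensitivity"]],
            specificity = cm[["specificity"]],
            accuracy = cm[["accuracy"]],
            threshold = thr$threshold,
            train_sensitivity = thr$achieved_sensitivity,
            n_train = data.table::uniqueN(d_tr$stay_id),
            n_test = data.table::uniqueN(d_te$stay_id),
            n_train_hours = nrow(d_tr), n_test_hours = nrow(d_te),
            seed = seed)
          if (keep_roc) roc[[cell]] <- roc_points(s_te, d_te$label)
        }
      }
    }
  }
  reports <- if (length(reports)) rbindlist(reports) else data.table()
  out <- list(reports = reports, roc = roc, skipped = skipped,
              split = split, comparison_note = comparison_note(reports))
  class(out) <- "slab_experiment"
  out
}

# flags the headline cross-definition pitfall: the best model on the worst
# definition underperforming the worst model on the best definition
comparison_note <- function(reports) {
  if (!nrow(reports) || data.table::uniqueN(reports$definition) < 2L)
    return(NA_character_)
  r <- reports[variant == reports$variant[1] &
                 horizon == reports$horizon[1] &
                 window_x == reports$window_x[1] &
                 window_y == reports$window_y[1]]
  by_def <- r[, .(best = max(auroc), worst = min(auroc)), by = definition]
  worst_def <- by_def$definition[which.min(by_def$best)]
  best_def <- by_def$definition[which.max(by_def$worst)]
  best_on_worst <- by_def[definition == worst_def, best]
  worst_on_best <- by_def[definition == best_def, worst]
  if (worst_def != best_def && best_on_worst < worst_on_best)
    sprintf(paste0("cross-definition caution: the best model under %s ",
                   "(AUROC %.3f) underperforms the worst model under %s ",
                   "(AUROC %.3f); model comparisons are only valid at a ",
                   "fixed onset definition"),
            worst_def, best_on_worst, best_def, worst_on_best)
  else
    "no cross-definition ranking inversion detected on this run"
}

#' @export
print.slab_experiment <- function(x, ...) {
  cat("<definition-sensitivity experiment>\n")
  if (nrow(x$reports)) {
    show <- x$reports[, .(definition, model, window_x, window_y, horizon,
                          variant, auroc = round(auroc, 3),
                          sensitivity = round(sensitivity, 3),
                          specificity = round(specificity, 3))]
    print(show)
  }
  if (!is.na(x$comparison_note)) cat(x$comparison_note, "\n")
  if (length(x$skipped))
    cat(sprintf("skipped cells: %s\n", paste(names(x$skipped), collapse = "; ")))
  invisible(x)
}
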