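#' Sepsis onset under a given definition
#'
#' Combines the suspicion time and the SOFA deterioration time into a
#' sepsis onset time. Sepsis requires both events, so the onset is `NA`
#' whenever either input is `NA`. The three competing definitions are:
#' `H1` -- onset at the organ-dysfunction time (`t_sofa`); `H2` -- onset at
#' the suspicion time (`t_suspicion`); `H3` -- the earlier of the two.
#'
#' @param t_suspicion,t_sofa Numeric vectors of event hours (`NA` = absent).
#' @param definition One of `"H1"`, `"H2"`, `"H3"`.
#' @return Numeric vector of onset hours (`NA` where undefined).
#' @export
assign_onset <- function(t_suspicion, t_sofa, definition = c("H1", "H2", "H3")) {
  if (length(definition) != 1L || !definition %in% c("H1", "H2", "H3"))
    stopf("configuration error: unknown sepsis onset definition '%s'",
          paste(definition, collapse = ","))
  both <- !is.na(t_suspicion) & !is.na(t_sofa)
  out <- rep(NA_real_, length(t_suspicion))
  out[both] <- switch(definition,
    H1 = t_sofa[both],
    H2 = t_suspicion[both],
    H3 = pmin(t_sofa[both], t_suspicion[both]))
  out
}

#' Label sepsis onsets for a cohort
#'
#' Full labeling pass: suspicion pairing, hourly SOFA trace, windowed
#' deterioration detection, and the three onset definitions. A stay with a
#' suspicion time but no in-window SOFA rise is treated as a control
#' (onset absent under every definition).
#'
#' @param stays,observations,doses,cultures Cohort tables (schema of
#'   [generate_cohort()]).
#' @param window A [sofa_window()].
#' @param include_other_specimens Include non-blood culture specimens in the
#'   suspicion pairing.
#' @param sofa Optional precomputed SOFA trace (from [compute_sofa()]) to
#'   avoid recomputation across windows.
#' @return `data.table` (`stay_id`, `x`, `y`, `t_suspicion`, `t_sofa`,
#'   `t_sepsis_h1`, `t_sepsis_h2`, `t_sepsis_h3`).
#' @export
label_onsets <- function(stays, observations, doses, cultures,
                         window = sofa_window(),
                         include_other_specimens = FALSE,
                         sofa = NULL) {
  susp <- compute_suspicion(doses, cultures, stays,
                            include_other_specimens)$suspicion
  if (is.null(sofa)) {
    grid <- build_hourly_grid(observations, stays)
    sofa <- compute_sofa(grid)
  }
  rec <- detect_tsofa_all(sofa, susp, window)
  rec[, `:=`(x = window$x, y = window$y,
             t_sepsis_h1 = assign_onset(t_suspicion, t_sofa, "H1"),
             t_sepsis_h2 = assign_onset(t_suspicion, t_sofa, "H2"),
             t_sepsis_h3 = assign_onset(t_suspicion, t_sofa, "H3"))]
  data.table::setcolorder(rec, c("stay_id", "x", "y", "t_suspicion", "t_sofa",
                                 "t_sepsis_h1", "t_sepsis_h2", "t_sepsis_h3"))
  rec[]
}

#' Cohort exclusion configuration
#'
#' @param min_los,max_los Length-of-stay bounds in hours (stays shorter than
#'   `min_los` or longer than `max_los` are excluded).
#' @param onset_grace Stays whose sepsis onset falls within this many hours
#'   of ICU admission are excluded (default 4 h).
#' @param exclude_pre_icu_abx Exclude stays with antibiotics before ICU.
#' @param excluded_units Care units to exclude.
#' @param exclude_elective_surgical Exclude elective surgical admissions.
#' @param require_any_vitals Exclude stays with no vital-sign observations.
#' @param strict_h3_grace Apply the early-onset grace rule using the H3
#'   onset (the strictest definition) regardless of the cohort's own
#'   definition, so H1/H2 cohorts share H3's exclusions.
#' @return A list of class `slab_exclusion_config`.
#' @export
exclusion_config <- function(min_los = 4, max_los = 480, onset_grace = 4,
                             exclude_pre_icu_abx = TRUE,
                             excluded_units = "cardiothoracic surgical",
                             exclude_elective_surgical = TRUE,
                             require_any_vitals = TRUE,
                             strict_h3_grace = FALSE) {
  if (min_los >= max_los) stopf("exclusion_config: min_los must be < max_los")
  if (onset_grace < 0) stopf("exclusion_config: onset_grace must be >= 0")
  structure(list(min_los = min_los, max_los = max_los,
                 onset_grace = onset_grace,
                 exclude_pre_icu_abx = exclude_pre_icu_abx,
                 excluded_units = excluded_units,
                 exclude_elective_surgical = exclude_elective_surgical,
                 require_any_vitals = require_any_vitals,
                 strict_h3_grace = strict_h3_grace),
            class = "slab_exclusion_config")
}

EXCLUSION_REASONS <- c("pre_icu_antibiotics", "excluded_care_unit",
                       "elective_surgical", "los_out_of_bounds",
                       "all_vitals_missing", "early_onset",
                       "duplicate_patient")

#' Apply the cohort exclusion rules
#'
#' Rules fire in a fixed, documented order so that per-reason counts are
#' reproducible; each excluded stay carries the first reason that fired:
#' (1) pre-ICU antibiotics, (2) excluded care unit, (3) elective surgical,
#' (4) length-of-stay bounds, (5) all vital signs missing, (6) sepsis onset
#' within the grace period of admission (using the cohort definition's
#' onset, or H3's when `strict_h3_grace`), (7) more than one stay per
#' patient (earliest kept).
#'
#' @param stays Stay table.
#' @param onsets Onset table from [label_onsets()].
#' @param observations Observation table (for the vital-signs rule).
#' @param config An [exclusion_config()].
#' @param definition The cohort's onset definition (`"H1"`, `"H2"`, `"H3"`).
#' @return `data.table` (`stay_id`, `included`, `exclusion_reason`,
#'   `t_sepsis`) with per-reason counts in attribute `"flow"`.
#' @export
apply_exclusions <- function(stays, onsets, observations,
                             config = exclusion_config(),
                             definition = c("H1", "H2", "H3")) {
  definition <- match.arg(definition)
  stays <- data.table::as.data.table(stays)
  if (!"los_hours" %in% names(stays))
    stays[, los_hours := as.numeric(icu_out_time - icu_in_time)]
  if (!setequal(stays$stay_id, onsets$stay_id))
    stopf("contract violation: stays and onsets cover different stay_id sets")

  col <- paste0("t_sepsis_", tolower(definition))
  grace_col <- if (isTRUE(config$strict_h3_grace)) "t_sepsis_h3" else col
  ons <- data.table::as.data.table(onsets)
  res <- merge(stays, data.table(stay_id = ons$stay_id,
                                 t_sepsis = ons[[col]],
                                 t_grace = ons[[grace_col]]),
               by = "stay_id")

  has_vitals <- unique(data.table::as.data.table(observations)[
    variable %in% VITAL_VARIABLES, stay_id])

  res[, exclusion_reason := NA_character_]
  rule <- function(cond, reason)
    res[is.na(exclusion_reason) & cond, exclusion_reason := reason]
  if (isTRUE(config$exclude_pre_icu_abx))
    rule(res$pre_icu_antibiotics, "pre_icu_antibiotics")
  rule(res$care_unit %in% config$excluded_units, "excluded_care_unit")
  if (isTRUE(config$exclude_elective_surgical))
    rule(res$elective_surgical, "elective_surgical")
  rule(res$los_hours < config$min_los | res$los_hours > config$max_los,
       "los_out_of_bounds")
  if (isTRUE(config$require_any_vitals))
    rule(!res$stay_id %in% has_vitals, "all_vitals_missing")
  rule(!is.na(res$t_grace) & res$t_grace < config$onset_grace, "early_onset")
  # one stay per patient: keep the earliest surviving stay
  data.table::setorder(res, patient_id, icu_in_time, stay_id)
  res[is.na(exclusion_reason),
      exclusion_reason := ifelse(seq_len(.N) > 1L, "duplicate_patient",
                                 NA_character_),
      by = patient_id]
  res[, included := is.na(exclusion_reason)]

  flow <- table(factor(res$exclusion_reason, levels = EXCLUSION_REASONS))
  out <- res[, .(stay_id, included, exclusion_reason, t_sepsis)]
  data.table::setorder(out, stay_id)
  data.table::setattr(out, "flow",
    c(n_stays = nrow(out), as.list(flow), n_included = sum(out$included)))
  data.table::setattr(out, "definition", definition)
  out[]
}

#' Stratified train/test split
#'
#' Stays are stratified on sex, age quartile, length-of-stay quartile and
#' ever-ventilated status (quartiles computed on the full cohort), and each
#' stratum is split with the requested train fraction (within one patient).
#' Strata of size one go to the training set with a warning. The split is
#' intended to be assigned *before* exclusions are applied.
#'
#' @param stays Stay table.
#' @param train_fraction Proportion assigned to training (default 0.85).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return `data.table` (`stay_id`, `split`) with `split` in
#'   `{"train", "test"}`.
#' @export
split_train_test <- function(stays, train_fraction = 0.85, seed = 1L) {
  stays <- data.table::as.data.table(stays)
  if (nrow(stays) == 0L) stopf("split_train_test: empty stay table")
  if (!"los_hours" %in% names(stays))
    stays[, los_hours := as.numeric(icu_out_time - icu_in_time)]
  qage <- quantile(stays$age, c(0.25, 0.5, 0.75), type = 7)
  qlos <- quantile(stays$los_hours, c(0.25, 0.5, 0.75), type = 7)
  s <- stays[, .(stay_id, sex, ever_ventilated,
                 age_q = findInterval(age, qage),
                 los_q = findInterval(los_hours, qlos))]
  s[, stratum := paste(sex, age_q, los_q, ever_ventilated, sep = "|")]
  data.table::setorder(s, stay_id)
  singletons <- s[, .N, by = stratum][N == 1L]
  if (nrow(singletons) > 0L)
    warning(sprintf("%d stratum/strata of size 1 assigned to train",
                    nrow(singletons)), call. = FALSE)
  data.table::setorder(s, stratum, stay_id)
  with_seed(seed, {
    s[, split := {
      # stochastic rounding keeps every stratum within one patient of the
      # target fraction without starving the test set in small strata
      n_exact <- train_fraction * .N
      n_tr <- if (.N == 1L) 1L
              else floor(n_exact) + rbinom(1L, 1L, n_exact - floor(n_exact))
      idx <- sample.int(.N)
      sp <- rep("test", .N)
      sp[idx <= n_tr] <- "train"
      sp
    }, by = stratum]
  })
  out <- s[, .(stay_id, split)]
  data.table::setorder(out, stay_id)
  out[]
}

#' Hourly prediction labels for a horizon
#'
#' Builds the patient-hour label table for the real-time prediction task.
#' For a septic stay with onset `s` (floored to the hourly grid), rows exist
#' only for hours strictly before `s`, and hour `h` is positive exactly when
#' the onset lies within the half-open lookahead `(h, h + T]`; the positive
#' rows per septic stay therefore number exactly `min(T, s)`. Non-septic
#' stays contribute every in-stay hour, labelled 0.
#'
#' @param stays Stay table (only stays present here get rows).
#' @param onsets Onset table from [label_onsets()].
#' @param definition Onset definition selecting the `t_sepsis` column.
#' @param horizon Prediction horizon T in hours (>= 1).
#' @return `data.table` (`stay_id`, `hour`, `label`), attribute `"horizon"`.
#' @export
make_hourly_labels <- function(stays, onsets, definition = c("H1", "H2", "H3"),
                               horizon = 6) {
  definition <- match.arg(definition)
  if (!is.numeric(horizon) || horizon < 1) stopf("horizon must be >= 1")
  stays <- data.table::as.data.table(stays)
  if (!"los_hours" %in% names(stays))
    stays[, los_hours := as.numeric(icu_out_time - icu_in_time)]
  col <- paste0("t_sepsis_", tolower(definition))
  d <- merge(stays[, .(stay_id, los_hours)],
             data.table::as.data.table(onsets)[, .(stay_id, t_sepsis = get(col))],
             by = "stay_id")
  d[, t_sepsis := floor(t_sepsis)]
  if (any(!is.na(d$t_sepsis) & d$t_sepsis < 1))
    stopf("contract violation: septic stay with onset before the first grid hour; such stays must be excluded upstream")
  lab <- d[, {
    n_h <- if (is.na(t_sepsis)) max(floor(los_hours), 0) else t_sepsis
    if (n_h < 1) list(hour = integer(), label = integer())
    else {
      h <- 0:(n_h - 1)
      l <- if (is.na(t_sepsis)) rep(0L, length(h))
           else as.integer(t_sepsis - h <= horizon)
      list(hour = h, label = l)
    }
  }, by = stay_id]
  data.table::setattr(lab, "horizon", horizon)
  lab[]
}
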