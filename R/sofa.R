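#' Build the forward-filled hourly grid
#'
#' Places every observation on an hourly grid (hour `h` summarises the
#' interval `[h, h+1)`) and forward-fills: the cell for variable `v` at hour
#' `h` holds the last observed value at or before the end of hour `h`.
#' Cells before a variable's first observation are left `NA` ("absent"); the
#' SOFA engine scores absent inputs as zero contribution. Ties within an
#' hour are resolved by the latest observation in that hour. No staleness
#' limit is applied to the forward fill.
#'
#' `urine_output` is special-cased: its hourly cell is the *sum* of the
#' amounts recorded in that hour (zero for hours without a record once the
#' stay has any urine record), since the renal SOFA band is defined on
#' 24-hour totals.
#'
#' @param observations Long table (`stay_id`, `variable`, `time`, `value`).
#' @param stays Stay table with `stay_id` and `los_hours` (or
#'   `icu_in_time`/`icu_out_time`).
#' @return A wide `data.table` keyed by (`stay_id`, `hour`) with one column
#'   per variable in [variable_definitions()]; hours run 0 to
#'   `floor(los) - 1`.
#' @export
build_hourly_grid <- function(observations, stays) {
  assert_columns(stays, "stay_id", "stays")
  if (!"los_hours" %in% names(stays))
    stays <- data.table::as.data.table(stays)[, los_hours := as.numeric(icu_out_time - icu_in_time)]
  obs <- data.table::as.data.table(observations)
  if (nrow(obs)) {
    assert_columns(obs, c("stay_id", "variable", "time", "value"), "observations")
    if (any(obs$time < 0)) stopf("contract violation: negative observation times")
    bad <- !obs$stay_id %in% stays$stay_id
    if (any(bad)) stopf("contract violation: observations for unknown stay_id(s): %s",
                        paste(unique(obs$stay_id[bad]), collapse = ", "))
  }

  vars <- variable_definitions()$variable
  grid <- stays[, .(hour = seq_len(max(floor(los_hours), 1)) - 1L), by = stay_id]

  if (nrow(obs) == 0L) {
    for (v in vars) grid[, (v) := NA_real_]
    data.table::setkey(grid, stay_id, hour)
    return(grid[])
  }

  obs <- obs[variable %in% vars]
  obs[, hour := as.integer(floor(time))]

  # urine output: per-hour sums
  ur <- obs[variable == "urine_output",
            .(urine_output = sum(value)), by = .(stay_id, hour)]
  # everything else: last value within each hour, then forward fill
  pt <- obs[variable != "urine_output"]
  data.table::setorder(pt, stay_id, variable, time)
  pt <- pt[, .(value = value[.N]), by = .(stay_id, variable, hour)]
  wide <- data.table::dcast(pt, stay_id + hour ~ variable, value.var = "value")

  grid <- merge(grid, wide, by = c("stay_id", "hour"), all.x = TRUE)
  fill_vars <- intersect(names(wide), setdiff(vars, "urine_output"))
  if (length(fill_vars))
    grid[, (fill_vars) := lapply(.SD, data.table::nafill, type = "locf"),
         by = stay_id, .SDcols = fill_vars]

  grid <- merge(grid, ur, by = c("stay_id", "hour"), all.x = TRUE)
  if (nrow(ur)) {
    # stays with any urine record: absent hours count as 0 output
    has_ur <- unique(ur$stay_id)
    grid[stay_id %in% has_ur & is.na(urine_output), urine_output := 0]
  }
  for (v in setdiff(vars, names(grid))) grid[, (v) := NA_real_]
  data.table::setcolorder(grid, c("stay_id", "hour", vars))
  data.table::setkey(grid, stay_id, hour)
  grid[]
}

# ---- SOFA component scoring (standard published thresholds) --------------

sofa_respiration <- function(pf, vent) {
  vent <- !is.na(vent) & vent >= 0.5
  s <- rep(0L, length(pf))
  ok <- !is.na(pf)
  s[ok & pf < 400] <- 1L
  s[ok & pf < 300] <- 2L
  s[ok & pf < 200 & vent] <- 3L
  s[ok & pf < 100 & vent] <- 4L
  s
}

sofa_coagulation <- function(platelets) {
  s <- rep(0L, length(platelets))
  ok <- !is.na(platelets)
  s[ok & platelets < 150] <- 1L
  s[ok & platelets < 100] <- 2L
  s[ok & platelets < 50] <- 3L
  s[ok & platelets < 20] <- 4L
  s
}

sofa_liver <- function(bilirubin) {
  s <- rep(0L, length(bilirubin))
  ok <- !is.na(bilirubin)
  s[ok & bilirubin >= 1.2] <- 1L
  s[ok & bilirubin >= 2.0] <- 2L
  s[ok & bilirubin >= 6.0] <- 3L
  s[ok & bilirubin >= 12.0] <- 4L
  s
}

sofa_cardiovascular <- function(map, dopamine, norepinephrine) {
  s <- rep(0L, length(map))
  s[!is.na(map) & map < 70] <- 1L
  dop <- ifelse(is.na(dopamine), 0, dopamine)
  nor <- ifelse(is.na(norepinephrine), 0, norepinephrine)
  s[dop > 0 & dop <= 5] <- pmax(s[dop > 0 & dop <= 5], 2L)
  s[(dop > 5 & dop <= 15) | (nor > 0 & nor <= 0.1)] <-
    pmax(s[(dop > 5 & dop <= 15) | (nor > 0 & nor <= 0.1)], 3L)
  s[dop > 15 | nor > 0.1] <- 4L
  s
}

sofa_cns <- function(gcs) {
  s <- rep(0L, length(gcs))
  ok <- !is.na(gcs)
  s[ok & gcs <= 14] <- 1L
  s[ok & gcs <= 12] <- 2L
  s[ok & gcs <= 9] <- 3L
  s[ok & gcs <= 5] <- 4L
  s
}

sofa_renal <- function(creatinine, urine_24h) {
  s <- rep(0L, length(creatinine))
  ok <- !is.na(creatinine)
  s[ok & creatinine >= 1.2] <- 1L
  s[ok & creatinine >= 2.0] <- 2L
  s[ok & creatinine >= 3.5] <- 3L
  s[ok & creatinine >= 5.0] <- 4L
  uo <- !is.na(urine_24h)
  s[uo & urine_24h < 500] <- pmax(s[uo & urine_24h < 500], 3L)
  s[uo & urine_24h < 200] <- 4L
  s
}

#' Hourly six-component SOFA trace
#'
#' Scores each grid hour with the standard SOFA thresholds: respiration
#' (PaO2/FiO2, scores 3-4 requiring the ventilation flag), coagulation
#' (platelets), liver (bilirubin), cardiovascular (MAP < 70 and
#' dopamine/norepinephrine dose bands), CNS (GCS) and renal (the worse of
#' the creatinine band and the rolling 24-hour urine-output band, the latter
#' contributing only once a full 24 hours of data exist). A variable that
#' has not yet been observed contributes zero to its subscore.
#'
#' @param grid Hourly grid from [build_hourly_grid()].
#' @return `data.table` (`stay_id`, `hour`, six subscore columns, `total`).
#' @export
compute_sofa <- function(grid) {
  assert_columns(grid, c("stay_id", "hour", "pao2", "fio2", "vent",
                         "platelets", "bilirubin", "map", "dopamine",
                         "norepinephrine", "gcs", "creatinine",
                         "urine_output"), "grid")
  for (v in c("platelets", "bilirubin", "creatinine", "pao2", "fio2")) {
    bad <- which(!is.na(grid[[v]]) & grid[[v]] < 0)
    if (length(bad))
      stopf("validation error: negative %s at grid row(s) %s", v,
            paste(head(bad, 5), collapse = ", "))
  }
  g <- data.table::copy(data.table::as.data.table(grid))
  data.table::setorder(g, stay_id, hour)  # rolling urine needs hour order
  tr <- g[, .(stay_id, hour)]
  pf <- g$pao2 / g$fio2
  g[, urine_24h := data.table::frollsum(urine_output, 24, na.rm = FALSE),
    by = stay_id]
  tr[, respiration := sofa_respiration(pf, g$vent)]
  tr[, coagulation := sofa_coagulation(g$platelets)]
  tr[, liver := sofa_liver(g$bilirubin)]
  tr[, cardiovascular := sofa_cardiovascular(g$map, g$dopamine, g$norepinephrine)]
  tr[, cns := sofa_cns(g$gcs)]
  tr[, renal := sofa_renal(g$creatinine, g$urine_24h)]
  tr[, total := respiration + coagulation + liver + cardiovascular + cns + renal]
  tr[]
}

#' SOFA deterioration window
#'
#' The interval around the suspicion time searched for a SOFA rise:
#' `x` hours before to `y` hours after.
#' @param x,y Non-negative hours before/after the suspicion time.
#' @return A list of class `slab_sofa_window`.
#' @export
sofa_window <- function(x = 24, y = 12) {
  if (!is.numeric(x) || !is.numeric(y) || is.na(x) || is.na(y) || x < 0 || y < 0)
    stopf("sofa_window: x and y must be non-negative hours")
  structure(list(x = x, y = y), class = "slab_sofa_window")
}

#' Detect the SOFA deterioration time for one stay
#'
#' Restricts the hourly SOFA trace to
#' `[max(0, t_suspicion - x), min(end of stay, t_suspicion + y)]`, takes the
#' total at the first hour of that restricted interval as the initial value,
#' and returns the earliest hour at which the total is at least two points
#' above it (`NA` if none, or if the restricted interval is empty).
#'
#' @param trace A single stay's SOFA trace (`hour`, `total`).
#' @param t_suspicion Suspicion time in hours.
#' @param window A [sofa_window()].
#' @param rise Required rise above the initial value (default 2).
#' @return The deterioration hour, or `NA_real_`.
#' @export
detect_tsofa <- function(trace, t_suspicion, window = sofa_window(), rise = 2) {
  if (is.na(t_suspicion)) return(NA_real_)
  hrs <- trace$hour
  keep <- hrs >= max(0, t_suspicion - window$x) & hrs <= t_suspicion + window$y
  if (!any(keep)) return(NA_real_)
  h <- hrs[keep]
  tot <- trace$total[keep]
  o <- order(h)
  h <- h[o]; tot <- tot[o]
  init <- tot[1]
  idx <- which(tot >= init + rise)
  if (!length(idx)) NA_real_ else as.numeric(h[idx[1]])
}

#' Detect t_sofa for every stay with a suspicion time
#'
#' @param sofa A SOFA trace table from [compute_sofa()] (all stays).
#' @param suspicion Table (`stay_id`, `t_suspicion`); `NA` rows pass through.
#' @param window A [sofa_window()].
#' @return `data.table` (`stay_id`, `t_suspicion`, `t_sofa`).
#' @export
detect_tsofa_all <- function(sofa, suspicion, window = sofa_window()) {
  assert_columns(suspicion, c("stay_id", "t_suspicion"), "suspicion")
  res <- data.table::as.data.table(suspicion)[, .(stay_id, t_suspicion)]
  traces <- split(sofa, by = "stay_id", keep.by = FALSE)
  res[, t_sofa := vapply(seq_len(.N), function(i) {
    tr <- traces[[stay_id[i]]]
    if (is.null(tr)) return(NA_real_)
    detect_tsofa(tr, t_suspicion[i], window)
  }, numeric(1))]
  res[]
}
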