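#' Partition antibiotic doses into courses
#'
#' Doses of the same drug for the same stay are walked in time order and
#' split greedily: a new course starts whenever the gap to the previous dose
#' exceeds 48 hours (a gap of exactly 48 hours stays in-course). Only the
#' initial time of each course is later considered as a candidate antibiotic
#' start.
#'
#' @param doses Table (`stay_id`, `drug_name`, `time`).
#' @param max_gap Maximum in-course gap between consecutive doses (hours).
#' @return `data.table` (`stay_id`, `drug_name`, `course_id`, `start_time`,
#'   `n_doses`), one row per course.
#' @export
build_courses <- function(doses, max_gap = 48) {
  doses <- data.table::as.data.table(doses)
  if (nrow(doses) == 0L)
    return(data.table(stay_id = character(), drug_name = character(),
                      course_id = integer(), start_time = numeric(),
                      n_doses = integer()))
  assert_columns(doses, c("stay_id", "drug_name", "time"), "doses")
  if (any(is.na(doses$drug_name)) || any(!nzchar(doses$drug_name)))
    stopf("doses: drug_name must be non-empty")
  data.table::setorder(doses, stay_id, drug_name, time)
  doses[, gap := time - data.table::shift(time), by = .(stay_id, drug_name)]
  doses[, course_id := cumsum(is.na(gap) | gap > max_gap), by = .(stay_id, drug_name)]
  doses[, .(start_time = time[1], n_doses = .N),
        by = .(stay_id, drug_name, course_id)]
}

#' Qualifying antibiotic start times
#'
#' A course start `s` counts towards suspicion of infection only if at least
#' two antibiotic doses -- pooled across every drug given to the stay --
#' fall within `[s, s + 96]` hours. One-off prophylactic doses therefore
#' never qualify.
#'
#' @param courses Output of [build_courses()].
#' @param doses The full dose table (all drugs) used for the pooled count.
#' @param qualify_window Width of the counting window (hours).
#' @param min_doses Minimum pooled dose count required.
#' @return `data.table` (`stay_id`, `t_abx`), ascending within stay.
#' @export
qualifying_abx_times <- function(courses, doses, qualify_window = 96,
                                 min_doses = 2L) {
  if (nrow(courses) == 0L)
    return(data.table(stay_id = character(), t_abx = numeric()))
  doses <- data.table::as.data.table(doses)
  out <- courses[, {
    dt_stay <- doses[stay_id == .BY$stay_id, time]
    keep <- vapply(start_time, function(s)
      sum(dt_stay >= s & dt_stay <= s + qualify_window) >= min_doses, logical(1))
    list(t_abx = sort(start_time[keep]))
  }, by = stay_id]
  out[]
}

#' Pair antibiotic starts with culture draws
#'
#' A qualifying antibiotic start and a culture draw constitute a suspicion
#' of infection when they are close enough in the direction-dependent sense:
#' antibiotic first requires the culture within 24 hours; culture first
#' requires the antibiotic within 72 hours (boundaries inclusive;
#' simultaneous events are treated as antibiotic-first). Each valid pair
#' yields an episode whose suspicion time is the earlier of the two events.
#'
#' @param abx Table (`stay_id`, `t_abx`) of qualifying antibiotic starts.
#' @param cultures Table (`stay_id`, `specimen_type`, `time`).
#' @param include_other_specimens If `FALSE` (default) only blood cultures
#'   are considered; if `TRUE`, all specimen types.
#' @param abx_first_max,cult_first_max Proximity bounds in hours.
#' @return `data.table` (`stay_id`, `t_abx`, `t_cult`, `t_suspicion`),
#'   sorted by suspicion time within stay.
#' @export
pair_suspicion <- function(abx, cultures, include_other_specimens = FALSE,
                           abx_first_max = 24, cult_first_max = 72) {
  empty <- data.table(stay_id = character(), t_abx = numeric(),
                      t_cult = numeric(), t_suspicion = numeric())
  cultures <- data.table::as.data.table(cultures)
  abx <- data.table::as.data.table(abx)
  if (nrow(abx) == 0L || nrow(cultures) == 0L) return(empty)
  if (!include_other_specimens)
    cultures <- cultures[specimen_type == "blood"]
  if (nrow(cultures) == 0L) return(empty)
  pairs <- merge(abx[, .(stay_id, t_abx)],
                 cultures[, .(stay_id, t_cult = time)],
                 by = "stay_id", allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs[(t_abx <= t_cult & t_cult - t_abx <= abx_first_max) |
                 (t_cult < t_abx & t_abx - t_cult <= cult_first_max)]
  pairs[, t_suspicion := pmin(t_abx, t_cult)]
  data.table::setorder(pairs, stay_id, t_suspicion, t_abx, t_cult)
  pairs[]
}

#' Earliest suspicion time per stay
#'
#' @param episodes Output of [pair_suspicion()].
#' @param stays Optional stay table; stays without any episode are returned
#'   with `t_suspicion = NA`.
#' @return `data.table` (`stay_id`, `t_suspicion`).
#' @export
first_suspicion <- function(episodes, stays = NULL) {
  out <- if (nrow(episodes) == 0L)
    data.table(stay_id = character(), t_suspicion = numeric())
  else episodes[, .(t_suspicion = min(t_suspicion)), by = stay_id]
  if (!is.null(stays)) {
    out <- merge(data.table::as.data.table(stays)[, .(stay_id)], out,
                 by = "stay_id", all.x = TRUE)
  }
  out[]
}

#' Suspicion of infection for a whole cohort
#'
#' Convenience wrapper running [build_courses()], [qualifying_abx_times()],
#' [pair_suspicion()] and [first_suspicion()] in sequence.
#'
#' @inheritParams pair_suspicion
#' @param doses Dose table (`stay_id`, `drug_name`, `time`).
#' @param cultures Culture table (`stay_id`, `specimen_type`, `time`).
#' @param stays Optional stay table for NA-padding of suspicion-free stays.
#' @return List with `episodes` and `suspicion` tables.
#' @export
compute_suspicion <- function(doses, cultures, stays = NULL,
                              include_other_specimens = FALSE) {
  courses <- build_courses(doses)
  abx <- qualifying_abx_times(courses, doses)
  episodes <- pair_suspicion(abx, cultures, include_other_specimens)
  list(episodes = episodes,
       suspicion = first_suspicion(episodes, stays))
}
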