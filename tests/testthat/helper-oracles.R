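# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity by direct enumeration or closed form, never by
# calling the implementation under test.

# greedy course partition by explicit scan over the sorted dose times
bf_courses <- function(times, max_gap = 48) {
  times <- sort(times)
  if (!length(times)) return(list())
  courses <- list(times[1])
  for (t in times[-1]) {
    last <- courses[[length(courses)]]
    if (t - last[length(last)] <= max_gap)
      courses[[length(courses)]] <- c(last, t)
    else courses[[length(courses) + 1L]] <- t
  }
  courses
}

# course starts with >= min_doses pooled doses in [s, s + window]
bf_qualifying <- function(course_starts, all_times, window = 96, min_doses = 2) {
  ok <- vapply(course_starts, function(s)
    sum(all_times >= s & all_times <= s + window) >= min_doses, logical(1))
  sort(course_starts[ok])
}

# all-pairs enumeration of the 24 h / 72 h proximity rule
bf_episodes <- function(abx_times, cult_times) {
  out <- NULL
  for (a in abx_times) for (ct in cult_times) {
    valid <- if (a <= ct) ct - a <= 24 else a - ct <= 72
    if (valid) out <- rbind(out, data.frame(t_abx = a, t_cult = ct,
                                            t_suspicion = min(a, ct)))
  }
  if (is.null(out)) data.frame(t_abx = numeric(), t_cult = numeric(),
                               t_suspicion = numeric())
  else out[order(out$t_suspicion, out$t_abx, out$t_cult), , drop = FALSE]
}

# exhaustive in-window scan for the first >= initial + 2 hour
bf_tsofa <- function(hours, totals, t_susp, x, y, rise = 2) {
  keep <- hours >= max(0, t_susp - x) & hours <= t_susp + y
  if (!any(keep)) return(NA_real_)
  h <- hours[keep][order(hours[keep])]
  tot <- totals[keep][order(hours[keep])]
  for (i in seq_along(h)) if (tot[i] >= tot[1] + rise) return(as.numeric(h[i]))
  NA_real_
}

# O(n^2) pair-counting AUROC with half credit for ties
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact level-1/level-2 signature of a piecewise-linear path by direct
# Riemann-Stieltjes integration (the trapezoid rule is exact per segment
# because the integrand is linear in t on each segment)
bf_signature2 <- function(path) {
  path <- as.matrix(path)
  d <- ncol(path); m <- nrow(path)
  s1 <- path[m, ] - path[1, ]
  s2 <- matrix(0, d, d)
  for (seg in seq_len(m - 1)) {
    dx <- path[seg + 1, ] - path[seg, ]
    xbar <- (path[seg + 1, ] + path[seg, ]) / 2 - path[1, ]
    s2 <- s2 + outer(xbar, dx)
  }
  list(level1 = s1, level2 = s2)
}

# SOFA subscores transcribed independently as cut() lookups
bf_sofa <- function(pf, vent, platelets, bilirubin, map, dopamine,
                    norepinephrine, gcs, creatinine, urine24) {
  band <- function(x, breaks, scores_right) {
    if (is.na(x)) return(0L)
    scores_right[findInterval(x, breaks) + 1L]
  }
  resp <- if (is.na(pf)) 0L else {
    r <- band(pf, c(100, 200, 300, 400), c(4L, 3L, 2L, 1L, 0L))
    if (r >= 3L && !isTRUE(vent >= 0.5)) 2L else r
  }
  coag <- band(platelets, c(20, 50, 100, 150), c(4L, 3L, 2L, 1L, 0L))
  liver <- band(bilirubin, c(1.2, 2, 6, 12), c(0L, 1L, 2L, 3L, 4L))
  cardio <- 0L
  if (!is.na(map) && map < 70) cardio <- 1L
  dop <- if (is.na(dopamine)) 0 else dopamine
  nor <- if (is.na(norepinephrine)) 0 else norepinephrine
  if (dop > 0) cardio <- max(cardio, if (dop > 15) 4L else if (dop > 5) 3L else 2L)
  if (nor > 0) cardio <- max(cardio, if (nor > 0.1) 4L else 3L)
  cns <- band(gcs, c(6, 10, 13, 15), c(4L, 3L, 2L, 1L, 0L))
  renal <- band(creatinine, c(1.2, 2, 3.5, 5), c(0L, 1L, 2L, 3L, 4L))
  if (!is.na(urine24))
    renal <- max(renal, if (urine24 < 200) 4L else if (urine24 < 500) 3L else 0L)
  c(respiration = resp, coagulation = coag, liver = liver,
    cardiovascular = cardio, cns = cns, renal = renal)
}

# small deterministic cohort shared by several test files
tiny_cohort <- function(n = 40, septic = 0.3, seed = 404) {
  generate_cohort(cohort_config(n_patients = n, septic_fraction = septic,
                                seed = seed))
}

random_sofa_trace <- function(n_hours, seed_vals) {
  data.table::data.table(hour = 0:(n_hours - 1), total = seed_vals)
}
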