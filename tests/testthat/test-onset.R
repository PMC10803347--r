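test_that("the three onset definitions combine suspicion and SOFA times", {
  expect_equal(assign_onset(20, 15, "H1"), 15)
  expect_equal(assign_onset(20, 15, "H2"), 20)
  expect_equal(assign_onset(20, 15, "H3"), 15)
  # both events are required
  expect_true(is.na(assign_onset(20, NA, "H1")))
  expect_true(is.na(assign_onset(20, NA, "H2")))
  expect_true(is.na(assign_onset(NA, 15, "H3")))
  expect_error(assign_onset(1, 2, "H4"), "configuration error")
})

test_that("H3 equals the elementwise minimum of H1 and H2 on random pairs", {
  set.seed(71)
  ts <- ifelse(runif(500) < 0.2, NA, runif(500, 0, 100))
  tf <- ifelse(runif(500) < 0.2, NA, runif(500, 0, 100))
  h1 <- assign_onset(ts, tf, "H1")
  h2 <- assign_onset(ts, tf, "H2")
  h3 <- assign_onset(ts, tf, "H3")
  expect_equal(h3, pmin(h1, h2))
  expect_equal(is.na(h3), is.na(h1) | is.na(h2))
})

toy_stays <- function() {
  data.table::data.table(
    patient_id = paste0("P", 1:8),
    stay_id = paste0("S", 1:8),
    icu_in_time = 0,
    icu_out_time = c(100, 100, 2, 720, 100, 100, 100, 100),
    los_hours = c(100, 100, 2, 720, 100, 100, 100, 100),
    age = 50, sex = "F",
    care_unit = c("medical", "cardiothoracic surgical", rep("medical", 6)),
    elective_surgical = FALSE,
    pre_icu_antibiotics = c(TRUE, rep(FALSE, 7)),
    pre_icu_hours = 0,
    ever_ventilated = FALSE)
}

toy_onsets <- function(t1 = NA_real_, t2 = NA_real_, t3 = NA_real_, n = 8) {
  data.table::data.table(
    stay_id = paste0("S", 1:n), x = 24, y = 12,
    t_suspicion = NA_real_, t_sofa = NA_real_,
    t_sepsis_h1 = rep(t1, n), t_sepsis_h2 = rep(t2, n),
    t_sepsis_h3 = rep(t3, n))
}

toy_obs <- function(skip_stay = "S5") {
  st <- setdiff(paste0("S", 1:8), skip_stay)
  data.table::data.table(stay_id = st, variable = "heart_rate",
                         time = 1, value = 80)
}

test_that("exclusion rules fire in the documented order on a toy cohort", {
  asm <- apply_exclusions(toy_stays(), toy_onsets(), toy_obs("S5"),
                          exclusion_config(), "H1")
  expect_equal(sum(asm$included), 3L)  # S6, S7, S8 are clean
  r <- setNames(asm$exclusion_reason, asm$stay_id)
  expect_equal(unname(r["S1"]), "pre_icu_antibiotics")
  expect_equal(unname(r["S2"]), "excluded_care_unit")
  expect_equal(unname(r["S3"]), "los_out_of_bounds")
  expect_equal(unname(r["S4"]), "los_out_of_bounds")
  expect_equal(unname(r["S5"]), "all_vitals_missing")
  expect_true(all(is.na(r[c("S6", "S7", "S8")])))
  # flow counts partition the excluded set
  flow <- attr(asm, "flow")
  n_reasons <- sum(unlist(flow[sepsislab:::EXCLUSION_REASONS]))
  expect_equal(n_reasons + flow$n_included, flow$n_stays)
})

test_that("early-onset grace excludes onsets inside four hours", {
  on <- toy_onsets(t1 = 3, t2 = 10, t3 = 3)
  asm <- apply_exclusions(toy_stays(), on, toy_obs(), exclusion_config(), "H1")
  expect_true(all(asm$exclusion_reason[asm$stay_id %in% paste0("S", 6:8)] ==
                    "early_onset"))
  # under H2 the same stays survive the grace rule (onset at 10 h)
  asm2 <- apply_exclusions(toy_stays(), on, toy_obs(), exclusion_config(), "H2")
  expect_true(all(asm2$included[asm2$stay_id %in% paste0("S", 6:8)]))
  # the strict variant applies H3's grace to the H2 cohort
  asm3 <- apply_exclusions(toy_stays(), on, toy_obs(),
                           exclusion_config(strict_h3_grace = TRUE), "H2")
  expect_true(all(asm3$exclusion_reason[asm3$stay_id %in% paste0("S", 6:8)] ==
                    "early_onset"))
  # onset exactly at the grace boundary is retained
  on4 <- toy_onsets(t1 = 4, t2 = 4, t3 = 4)
  asm4 <- apply_exclusions(toy_stays(), on4, toy_obs(), exclusion_config(), "H1")
  expect_true(all(asm4$included[asm4$stay_id %in% paste0("S", 6:8)]))
})

test_that("one stay per patient: the earliest surviving stay is kept", {
  st <- toy_stays()[6:7]
  st$patient_id <- "P9"
  st$icu_in_time <- c(5, 0)
  on <- toy_onsets(n = 8)[6:7]
  obs <- data.table::data.table(stay_id = c("S6", "S7"),
                                variable = "heart_rate", time = 1, value = 80)
  asm <- apply_exclusions(st, on, obs, exclusion_config(), "H1")
  expect_equal(asm$stay_id[asm$included], "S7")
  expect_equal(asm$exclusion_reason[asm$stay_id == "S6"], "duplicate_patient")
})

test_that("H3's early-onset exclusion removes a superset of H1's and H2's", {
  co <- tiny_cohort(n = 60, septic = 0.4, seed = 81)
  on <- label_onsets(co$stays, co$observations, co$dose_events,
                     co$culture_events)
  excl <- function(def) {
    a <- apply_exclusions(co$stays, on, co$observations, exclusion_config(),
                          def)
    a$stay_id[!is.na(a$exclusion_reason) & a$exclusion_reason == "early_onset"]
  }
  e3 <- excl("H3")
  expect_true(all(excl("H1") %in% e3))
  expect_true(all(excl("H2") %in% e3))
})

test_that("stratified split is deterministic and respects stratum fractions", {
  co <- tiny_cohort(n = 200, septic = 0.2, seed = 82)
  s1 <- suppressWarnings(split_train_test(co$stays, 0.85, seed = 9))
  s2 <- suppressWarnings(split_train_test(co$stays, 0.85, seed = 9))
  expect_identical(s1, s2)
  s3 <- suppressWarnings(split_train_test(co$stays, 0.85, seed = 10))
  expect_false(identical(s1, s3))
  expect_setequal(s1$split, c("train", "test"))
  # per-stratum train counts within one patient of the target fraction
  stays <- data.table::as.data.table(co$stays)
  qage <- quantile(stays$age, c(.25, .5, .75))
  qlos <- quantile(stays$los_hours, c(.25, .5, .75))
  stays[, stratum := paste(sex, findInterval(age, qage),
                           findInterval(los_hours, qlos), ever_ventilated)]
  m <- merge(stays[, .(stay_id, stratum)], s1, by = "stay_id")
  chk <- m[, .(n_tr = sum(split == "train"), n = .N), by = stratum]
  expect_true(all(abs(chk$n_tr - 0.85 * chk$n) <= 1))
})

test_that("a singleton stratum goes to train with a warning", {
  st <- toy_stays()[6:8]
  st$age <- c(30, 30, 90)  # the 90-year-old is alone in its age stratum
  st$los_hours <- c(100, 100, 100)
  expect_warning(sp <- split_train_test(st, 0.85, seed = 1), "size 1")
  expect_true(all(c("train") %in% sp$split))
})

test_that("hourly labels follow the horizon example and closed-form count", {
  st <- data.table::data.table(patient_id = "P1", stay_id = "S1",
                               icu_in_time = 0, icu_out_time = 40,
                               los_hours = 40)
  on <- data.table::data.table(stay_id = "S1", t_suspicion = 21, t_sofa = 21,
                               t_sepsis_h1 = 21, t_sepsis_h2 = 21,
                               t_sepsis_h3 = 21)
  lab <- make_hourly_labels(st, on, "H1", horizon = 6)
  expect_equal(max(lab$hour), 20)  # no row at or after onset
  expect_equal(lab$hour[lab$label == 1], 15:20)
  expect_true(all(lab$label[lab$hour < 15] == 0))
  # non-septic stay contributes every in-stay hour, all zero
  on0 <- data.table::data.table(stay_id = "S1", t_suspicion = NA_real_,
                                t_sofa = NA_real_, t_sepsis_h1 = NA_real_,
                                t_sepsis_h2 = NA_real_, t_sepsis_h3 = NA_real_)
  lab0 <- make_hourly_labels(st, on0, "H1", horizon = 6)
  expect_equal(nrow(lab0), 40)
  expect_true(all(lab0$label == 0))
  expect_error(make_hourly_labels(st, on, "H1", horizon = 0), "horizon")
})

test_that("positive labels per septic stay number exactly min(T, onset)", {
  set.seed(83)
  for (i in 1:200) {
    onset <- sample(5:80, 1)
    T_h <- sample(1:24, 1)
    los <- onset + sample(0:50, 1)
    st <- data.table::data.table(patient_id = "P1", stay_id = "S1",
                                 icu_in_time = 0, icu_out_time = los,
                                 los_hours = los)
    on <- data.table::data.table(stay_id = "S1", t_suspicion = onset,
                                 t_sofa = onset, t_sepsis_h1 = onset,
                                 t_sepsis_h2 = onset, t_sepsis_h3 = onset)
    lab <- make_hourly_labels(st, on, "H1", horizon = T_h)
    expect_equal(sum(lab$label), min(T_h, onset))
    expect_true(all(lab$hour < onset))
  }
})

test_that("widening the SOFA window never converts a positive stay to negative", {
  co <- tiny_cohort(n = 50, septic = 0.4, seed = 84)
  grid <- build_hourly_grid(co$observations, co$stays)
  sofa <- compute_sofa(grid)
  narrow <- label_onsets(co$stays, co$observations, co$dose_events,
                         co$culture_events, sofa_window(12, 6), sofa = sofa)
  wide <- label_onsets(co$stays, co$observations, co$dose_events,
                       co$culture_events, sofa_window(48, 24), sofa = sofa)
  pos_narrow <- narrow$stay_id[!is.na(narrow$t_sepsis_h3)]
  pos_wide <- wide$stay_id[!is.na(wide$t_sepsis_h3)]
  expect_true(all(pos_narrow %in% pos_wide))
})
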