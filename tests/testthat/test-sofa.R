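make_stay <- function(los = 24, id = "S1") {
  data.table::data.table(stay_id = id, patient_id = paste0("P", id),
                         icu_in_time = 0, icu_out_time = los,
                         los_hours = los)
}

test_that("forward fill carries the last observation and respects absence", {
  stay <- make_stay(20)
  obs <- data.table::data.table(
    stay_id = "S1", variable = "platelets",
    time = c(2, 10), value = c(100, 40))
  g <- build_hourly_grid(obs, stay)
  expect_equal(nrow(g), 20)
  expect_true(all(is.na(g$platelets[g$hour < 2])))
  expect_true(all(g$platelets[g$hour >= 2 & g$hour <= 9] == 100))
  expect_true(all(g$platelets[g$hour >= 10] == 40))
  expect_true(all(is.na(g$heart_rate)))  # never observed
  # ties within an hour: the latest observation wins
  obs2 <- rbind(obs, data.table::data.table(stay_id = "S1",
                                            variable = "platelets",
                                            time = 2.7, value = 77))
  g2 <- build_hourly_grid(obs2, stay)
  expect_equal(g2$platelets[g2$hour == 2], 77)
  # empty observations: all-absent grid, no error
  g0 <- build_hourly_grid(obs[0], stay)
  expect_equal(nrow(g0), 20)
  expect_true(all(is.na(g0$map)))
  expect_error(build_hourly_grid(
    data.table::data.table(stay_id = "S1", variable = "map",
                           time = -1, value = 80), stay),
    "negative")
})

test_that("grid agrees with a brute-force last-value-at-or-before scan", {
  set.seed(91)
  for (rep in 1:20) {
    los <- sample(10:60, 1)
    stay <- make_stay(los)
    vars <- sample(c("heart_rate", "map", "platelets", "gcs", "bilirubin"),
                   3)
    obs <- data.table::rbindlist(lapply(vars, function(v) {
      k <- sample(0:8, 1)
      if (k == 0) return(NULL)
      data.table::data.table(stay_id = "S1", variable = v,
                             time = sort(runif(k, 0, los)),
                             value = round(runif(k, 10, 200), 1))
    }))
    if (is.null(obs) || nrow(obs) == 0) next
    g <- build_hourly_grid(obs, stay)
    for (v in vars) {
      ov <- obs[obs$variable == v]
      for (h in c(0, sample(0:(los - 1), 4, replace = TRUE))) {
        prior <- ov$value[floor(ov$time) <= h]
        tms <- ov$time[floor(ov$time) <= h]
        want <- if (length(prior)) prior[which.max(tms)] else NA_real_
        expect_identical(unname(g[[v]][g$hour == h]), want)
      }
    }
  }
})

test_that("grid causality: later observations never change earlier cells", {
  co <- tiny_cohort(n = 6, septic = 0.5, seed = 77)
  g_full <- build_hourly_grid(co$observations, co$stays)
  h_cut <- 24
  trunc <- co$observations[co$observations$time < h_cut + 1, ]
  g_trunc <- build_hourly_grid(trunc, co$stays)
  cols <- setdiff(names(g_full), c("stay_id", "hour"))
  expect_identical(as.data.frame(g_full[g_full$hour <= h_cut, cols, with = FALSE]),
                   as.data.frame(g_trunc[g_trunc$hour <= h_cut, cols, with = FALSE]))
})

test_that("subscores follow the published SOFA thresholds", {
  stay <- make_stay(3)
  base <- data.table::data.table(
    stay_id = "S1",
    variable = c("pao2", "fio2", "platelets", "bilirubin", "map", "gcs",
                 "creatinine"),
    time = 0.1,
    value = c(95, 0.21, 220, 0.8, 85, 15, 0.9))
  g <- compute_sofa(build_hourly_grid(base, stay))
  expect_true(all(g$total == 0))  # healthy baseline

  mod <- function(var, value) {
    o <- data.table::copy(base)
    o$value[o$variable == var] <- value
    compute_sofa(build_hourly_grid(o, stay))[hour == 1]
  }
  r <- mod("platelets", 90)
  expect_equal(r$coagulation, 2L); expect_equal(r$total, 2L)
  r <- mod("bilirubin", 7)
  expect_equal(r$liver, 3L); expect_equal(r$total, 3L)
  r <- mod("gcs", 8)
  expect_equal(r$cns, 3L); expect_equal(r$total, 3L)
  r <- mod("map", 60)
  expect_equal(r$cardiovascular, 1L); expect_equal(r$total, 1L)
  r <- mod("creatinine", 4)
  expect_equal(r$renal, 3L); expect_equal(r$total, 3L)
  # respiration 3 requires ventilation
  o <- data.table::copy(base); o$value[o$variable == "pao2"] <- 30
  o$value[o$variable == "fio2"] <- 0.2  # ratio 150
  expect_equal(compute_sofa(build_hourly_grid(o, stay))[hour == 1]$respiration, 2L)
  o <- rbind(o, data.table::data.table(stay_id = "S1", variable = "vent",
                                       time = 0.1, value = 1))
  r <- compute_sofa(build_hourly_grid(o, stay))[hour == 1]
  expect_equal(r$respiration, 3L); expect_equal(r$total, 3L)
  expect_error(mod("platelets", -5), "negative")
})

test_that("subscores match an independently transcribed threshold table", {
  set.seed(7)
  for (i in 1:500) {
    pf <- sample(c(NA, runif(1, 40, 500)), 1)
    vent <- sample(c(NA, 0, 1), 1)
    plat <- sample(c(NA, runif(1, 5, 400)), 1)
    bili <- sample(c(NA, runif(1, 0.1, 20)), 1)
    map <- sample(c(NA, runif(1, 40, 120)), 1)
    dop <- sample(c(NA, 0, runif(1, 0, 20)), 1)
    nor <- sample(c(NA, 0, runif(1, 0, 0.3)), 1)
    gcs <- sample(c(NA, sample(3:15, 1)), 1)
    crea <- sample(c(NA, runif(1, 0.3, 8)), 1)
    ur <- sample(c(NA, runif(1, 50, 3000)), 1)
    want <- bf_sofa(pf, vent, plat, bili, map, dop, nor, gcs, crea, ur)
    got <- c(
      respiration = sepsislab:::sofa_respiration(pf, vent),
      coagulation = sepsislab:::sofa_coagulation(plat),
      liver = sepsislab:::sofa_liver(bili),
      cardiovascular = sepsislab:::sofa_cardiovascular(map, dop, nor),
      cns = sepsislab:::sofa_cns(gcs),
      renal = sepsislab:::sofa_renal(crea, ur))
    expect_identical(unname(got), unname(want))
  }
})

test_that("total always equals the sum of the six subscores", {
  co <- tiny_cohort(n = 10, septic = 0.5, seed = 13)
  tr <- compute_sofa(build_hourly_grid(co$observations, co$stays))
  expect_true(all(tr$total == tr$respiration + tr$coagulation + tr$liver +
                    tr$cardiovascular + tr$cns + tr$renal))
  sub <- as.matrix(tr[, .(respiration, coagulation, liver, cardiovascular,
                          cns, renal)])
  expect_true(all(sub %in% 0:4))
})

test_that("urine-output renal band needs 24 h of data and uses 24 h totals", {
  stay <- make_stay(40)
  obs <- data.table::data.table(stay_id = "S1", variable = "urine_output",
                                time = seq(0.5, 39.5, by = 1), value = 15)
  tr <- compute_sofa(build_hourly_grid(obs, stay))
  expect_true(all(tr$renal[tr$hour < 23] == 0L))
  expect_true(all(tr$renal[tr$hour >= 23] == 3L))  # 360 mL/24h < 500
})

test_that("detect_tsofa matches the specification examples", {
  tr <- data.table::data.table(hour = 0:3, total = c(2, 2, 3, 4))
  expect_equal(detect_tsofa(tr, t_suspicion = 1, sofa_window(3, 3)), 3)
  flat <- data.table::data.table(hour = 0:10, total = rep(3, 11))
  expect_true(is.na(detect_tsofa(flat, 5, sofa_window(2, 2))))
  # empty restricted interval is absent, not an error
  expect_true(is.na(detect_tsofa(tr, t_suspicion = 50, sofa_window(2, 2))))
  expect_true(is.na(detect_tsofa(tr, NA_real_, sofa_window(2, 2))))
})

test_that("detect_tsofa equals the exhaustive in-window scan on random traces", {
  set.seed(402)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    tot <- pmax(0, pmin(24, cumsum(sample(-2:2, n, replace = TRUE)) +
                          sample(0:4, 1)))
    tr <- random_sofa_trace(n, tot)
    ts <- runif(1, -5, n + 5)
    w <- sofa_window(sample(0:48, 1), sample(0:24, 1))
    expect_identical(detect_tsofa(tr, ts, w),
                     bf_tsofa(tr$hour, tr$total, ts, w$x, w$y))
  }
})

test_that("enlarging y with x fixed never removes nor delays a detection", {
  set.seed(403)
  for (i in 1:200) {
    n <- sample(8:50, 1)
    tr <- random_sofa_trace(n, sample(0:10, n, replace = TRUE))
    ts <- runif(1, 0, n)
    x <- sample(0:24, 1); y <- sample(0:12, 1)
    t1 <- detect_tsofa(tr, ts, sofa_window(x, y))
    t2 <- detect_tsofa(tr, ts, sofa_window(x, y + sample(1:12, 1)))
    if (!is.na(t1)) {
      expect_false(is.na(t2))
      expect_lte(t2, t1)
    }
  }
})

test_that("compute_sofa is pointwise in patients", {
  co <- tiny_cohort(n = 8, septic = 0.5, seed = 19)
  g <- build_hourly_grid(co$observations, co$stays)
  t1 <- compute_sofa(g)
  g_perm <- g[sample(nrow(g)), ]
  t2 <- compute_sofa(g_perm)
  data.table::setorder(t1, stay_id, hour)
  data.table::setorder(t2, stay_id, hour)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})
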