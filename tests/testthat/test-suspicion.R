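dose_dt <- function(times, drug = "A", stay = "S1")
  data.table::data.table(stay_id = stay, drug_name = drug, time = times)

cult_dt <- function(times, type = "blood", stay = "S1")
  data.table::data.table(stay_id = stay, specimen_type = type, time = times)

test_that("course partitioning follows the 48-hour gap rule", {
  co <- build_courses(dose_dt(c(0, 30, 75)))
  expect_equal(nrow(co), 1L)
  expect_equal(co$start_time, 0)
  expect_equal(co$n_doses, 3L)
  co <- build_courses(dose_dt(c(0, 60)))
  expect_equal(co$start_time, c(0, 60))
  # boundary: a gap of exactly 48 h stays in-course
  expect_equal(nrow(build_courses(dose_dt(c(0, 48)))), 1L)
  expect_equal(nrow(build_courses(dose_dt(c(0, 48.01)))), 2L)
  # different drugs never share a course
  two <- rbind(dose_dt(c(0, 10), "A"), dose_dt(5, "B"))
  expect_equal(nrow(build_courses(two)), 2L)
  expect_equal(nrow(build_courses(dose_dt(numeric(0)))), 0L)
})

test_that("course partitioning equals the brute-force gap scan", {
  set.seed(55)
  for (i in 1:300) {
    times <- sort(round(runif(sample(1:9, 1), 0, 300), 1))
    got <- build_courses(dose_dt(times))
    want <- bf_courses(times)
    expect_equal(got$start_time, vapply(want, `[`, numeric(1), 1))
    expect_equal(got$n_doses, lengths(want), ignore_attr = TRUE)
  }
})

test_that("a qualifying antibiotic start needs two pooled doses in 96 h", {
  # one-off prophylactic dose never qualifies
  d <- dose_dt(10)
  expect_equal(nrow(qualifying_abx_times(build_courses(d), d)), 0L)
  # doses of different drugs pool
  d <- rbind(dose_dt(0, "A"), dose_dt(90, "B"))
  q <- qualifying_abx_times(build_courses(d), d)
  expect_true(0 %in% q$t_abx)
  # 96-h boundary inclusive
  d <- rbind(dose_dt(0, "A"), dose_dt(96, "B"))
  expect_true(0 %in% qualifying_abx_times(build_courses(d), d)$t_abx)
  d <- rbind(dose_dt(0, "A"), dose_dt(96.5, "B"))
  expect_false(0 %in% qualifying_abx_times(build_courses(d), d)$t_abx)
})

test_that("qualifying starts equal the brute-force count-in-interval oracle", {
  set.seed(56)
  for (i in 1:300) {
    d <- data.table::rbindlist(lapply(sample(1:3, 1), function(k)
      dose_dt(sort(round(runif(sample(1:6, 1), 0, 250), 1)),
              drug = sample(LETTERS[1:3], 1))))
    d <- unique(d)
    courses <- build_courses(d)
    got <- qualifying_abx_times(courses, d)$t_abx
    want <- bf_qualifying(courses$start_time, d$time)
    expect_equal(got, want)
  }
})

test_that("pairing applies the direction-dependent 24/72 h bounds", {
  abx <- data.table::data.table(stay_id = "S1", t_abx = 10)
  ep <- pair_suspicion(abx, cult_dt(30))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$t_suspicion, 10)
  # culture first, antibiotic 90 h later: out of bounds
  ep <- pair_suspicion(data.table::data.table(stay_id = "S1", t_abx = 100),
                       cult_dt(10))
  expect_equal(nrow(ep), 0L)
  # boundaries inclusive
  expect_equal(nrow(pair_suspicion(abx, cult_dt(34))), 1L)
  expect_equal(nrow(pair_suspicion(abx, cult_dt(34.5))), 0L)
  ep <- pair_suspicion(data.table::data.table(stay_id = "S1", t_abx = 82),
                       cult_dt(10))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$t_suspicion, 10)
  # non-blood specimens only when the flag is set
  expect_equal(nrow(pair_suspicion(abx, cult_dt(30, "other"))), 0L)
  expect_equal(nrow(pair_suspicion(abx, cult_dt(30, "other"),
                                   include_other_specimens = TRUE)), 1L)
  # simultaneous events count as antibiotic-first
  ep <- pair_suspicion(abx, cult_dt(10))
  expect_equal(ep$t_suspicion, 10)
})

test_that("episodes equal the exhaustive all-pairs enumeration", {
  set.seed(57)
  for (i in 1:1000) {
    abx_t <- sort(round(runif(sample(0:4, 1), 0, 200), 1))
    cult_t <- sort(round(runif(sample(0:4, 1), 0, 200), 1))
    abx <- data.table::data.table(stay_id = rep("S1", length(abx_t)),
                                  t_abx = abx_t)
    got <- pair_suspicion(abx, cult_dt(cult_t))
    want <- bf_episodes(abx_t, cult_t)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$t_suspicion, want$t_suspicion)
      expect_equal(sort(got$t_abx), sort(want$t_abx))
    }
    fs <- first_suspicion(got)
    if (nrow(want)) expect_equal(fs$t_suspicion, min(want$t_suspicion))
    else expect_equal(nrow(fs), 0L)
  }
})

test_that("first_suspicion returns the minimum and handles empties", {
  ep <- data.table::data.table(stay_id = "S1", t_abx = c(40, 12, 33),
                               t_cult = c(41, 13, 34),
                               t_suspicion = c(40, 12, 33))
  expect_equal(first_suspicion(ep)$t_suspicion, 12)
  stays <- data.table::data.table(stay_id = c("S1", "S2"))
  fs <- first_suspicion(ep, stays)
  expect_equal(fs$t_suspicion[fs$stay_id == "S2"], NA_real_)
})

test_that("adding cultures never removes episodes; removing antibiotics never adds", {
  set.seed(58)
  for (i in 1:150) {
    abx_t <- sort(runif(sample(1:4, 1), 0, 150))
    cult_t <- sort(runif(sample(1:4, 1), 0, 150))
    abx <- data.table::data.table(stay_id = rep("S1", length(abx_t)),
                                  t_abx = abx_t)
    base <- pair_suspicion(abx, cult_dt(cult_t))
    more <- pair_suspicion(abx, cult_dt(c(cult_t, runif(1, 0, 150))))
    expect_gte(nrow(more), nrow(base))
    if (nrow(base))
      expect_true(all(paste(base$t_abx, base$t_cult) %in%
                        paste(more$t_abx, more$t_cult)))
    fewer <- pair_suspicion(abx[-1, ], cult_dt(cult_t))
    expect_lte(nrow(fewer), nrow(base))
  }
})

test_that("including other specimens yields a superset and earlier-or-equal suspicion", {
  set.seed(59)
  for (i in 1:100) {
    abx_t <- sort(runif(2, 0, 100))
    cults <- rbind(cult_dt(sort(runif(2, 0, 100)), "blood"),
                   cult_dt(sort(runif(2, 0, 100)), "other"))
    abx <- data.table::data.table(stay_id = "S1", t_abx = abx_t)
    blood <- pair_suspicion(abx, cults, FALSE)
    all_sp <- pair_suspicion(abx, cults, TRUE)
    expect_gte(nrow(all_sp), nrow(blood))
    if (nrow(blood) && nrow(all_sp))
      expect_lte(min(all_sp$t_suspicion), min(blood$t_suspicion))
  }
})

test_that("suspicion times are equivariant under time translation", {
  set.seed(60)
  for (i in 1:100) {
    abx_t <- sort(runif(3, 0, 100))
    cult_t <- sort(runif(3, 0, 100))
    shift <- runif(1, 0, 50)
    abx <- data.table::data.table(stay_id = "S1", t_abx = abx_t)
    abx_s <- data.table::data.table(stay_id = "S1", t_abx = abx_t + shift)
    a <- pair_suspicion(abx, cult_dt(cult_t))
    b <- pair_suspicion(abx_s, cult_dt(cult_t + shift))
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) expect_equal(b$t_suspicion, a$t_suspicion + shift)
  }
})

test_that("full suspicion pass works per stay on a generated cohort", {
  co <- tiny_cohort(n = 30, septic = 0.4, seed = 61)
  s <- compute_suspicion(co$dose_events, co$culture_events, co$stays)
  expect_setequal(s$suspicion$stay_id, co$stays$stay_id)
  # every suspicion time is the minimum over that stay's episodes
  for (sid in unique(s$episodes$stay_id)) {
    expect_equal(s$suspicion$t_suspicion[s$suspicion$stay_id == sid],
                 min(s$episodes$t_suspicion[s$episodes$stay_id == sid]))
  }
})
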