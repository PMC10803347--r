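ABX_POOL <- c("vancomycin", "piperacillin-tazobactam", "cefepime",
              "meropenem", "levofloxacin", "ceftriaxone")

# deterioration ramp: 0 before onset, linear to 1 over ramp_hours, then flat
drift_ramp <- function(time, onset, ramp_hours) {
  pmin(pmax((time - onset) / ramp_hours, 0), 1)
}

# inflammatory variables whose drift begins at tau itself (the prodrome);
# all other drifting variables are organ-dysfunction markers that start at
# tau + organ lag
PRODROME_VARIABLES <- c("heart_rate", "resp_rate", "temp", "spo2", "wbc",
                        "lactate")

#' Sepsis deterioration deltas for an observation table
#'
#' Computes the additive physiological deterioration applied to a septic
#' stay's observations. The course has two phases: an inflammatory prodrome
#' (heart rate, respiratory rate, temperature, SpO2, white cells, lactate)
#' ramping from `tau` over `config$prodrome_ramp_hours`, and organ
#' dysfunction (MAP down, platelets down, bilirubin up, creatinine up, GCS
#' down, PaO2 down, ...) ramping from `tau + lag` over `config$ramp_hours`
#' to the full per-variable drift magnitude. Observations before the latent
#' infection time are untouched, so the pre-infection distribution is
#' identical to a non-septic stay.
#'
#' @param observations Long-format table with columns `variable`, `time`.
#' @param stay One-row stay table (needs `icu_out_time` relative hours, i.e.
#'   length of stay) used to validate that `tau` lies within the stay.
#' @param tau Latent infection time, hours since ICU admission.
#' @param config A [cohort_config()] (supplies drift magnitudes and ramp).
#' @param lag Hours from `tau` to the start of deterioration.
#' @return Numeric vector of deltas, one per observation row.
#' @export
inject_sepsis_trajectory <- function(observations, stay, tau, config, lag = 0) {
  assert_columns(observations, c("variable", "time"), "observations")
  los <- as.numeric(stay$icu_out_time - stay$icu_in_time)
  if (!is.numeric(tau) || is.na(tau) || tau < 0 || tau > los)
    stopf("tau (%.2f h) lies outside the stay [0, %.2f]", tau, los)
  if (any(!is.finite(config$drift_magnitudes)))
    stopf("drift magnitudes must be finite")
  mag <- config$drift_magnitudes[observations$variable]
  mag[is.na(mag)] <- 0
  prodrome <- observations$variable %in% PRODROME_VARIABLES
  ramp <- ifelse(prodrome,
                 drift_ramp(observations$time, tau,
                            config$prodrome_ramp_hours %||% config$ramp_hours),
                 drift_ramp(observations$time, tau + lag, config$ramp_hours))
  unname(mag * ramp)
}

# collapse possibly overlapping (start, end) episodes into change-point
# observations of a 0/1 state variable
episodes_to_obs <- function(starts, ends, los) {
  if (length(starts) == 0L) return(data.table(time = numeric(), value = numeric()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  m_start <- starts[1]; m_end <- ends[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= m_end) m_end <- max(m_end, ends[i])
    else { out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
           m_start <- starts[i]; m_end <- ends[i] }
  }
  out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
  keep <- out_s < los
  out_s <- pmax(out_s[keep], 0); out_e <- pmin(out_e[keep], los - 1e-6)
  data.table(time = c(out_s, out_e[out_e > out_s]),
             value = c(rep(1, length(out_s)), rep(0, sum(out_e > out_s))))
}

#' Generate a synthetic ICU cohort with known ground truth
#'
#' Emulates the statistical structure the onset-labeling and prediction
#' pipeline assumes: irregularly sampled vitals and labs, antibiotic dose
#' and microbiological culture event streams, ventilation and vasopressor
#' state records, stay-level metadata, and a latent per-patient infection
#' process whose true timings are recorded in a ground-truth table so that
#' label recovery and model performance can be verified without clinical
#' data.
#'
#' For septic patients a latent infection time tau is drawn; the first
#' antibiotic course and first culture draw are placed at configurable
#' offsets around tau, and physiological deterioration (via
#' [inject_sepsis_trajectory()]) begins after an organ lag. Non-septic
#' patients receive only background events: one-off antibiotic doses (which
#' never satisfy the two-dose qualification rule) and stand-alone cultures,
#' decoupled in time.
#'
#' @param config A [cohort_config()].
#' @return A list of class `slab_cohort` with `data.table`s `stays`,
#'   `observations`, `dose_events`, `culture_events`, `ground_truth`, and
#'   the `config` used.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "slab_generator_config"))
    stopf("config must be created by cohort_config()")
  defs <- variable_definitions()
  sampled_vars <- defs[!variable %in% STATE_VARIABLES]

  with_seed(config$seed, {
    n <- config$n_patients
    n_septic <- round(config$septic_fraction * n)
    septic_ids <- if (n_septic > 0) sort(sample.int(n, n_septic)) else integer()

    los <- runif(n, config$los_range_hours[1], config$los_range_hours[2])
    stays <- data.table(
      patient_id = sprintf("P%04d", seq_len(n)),
      stay_id = sprintf("S%04d", seq_len(n)),
      icu_in_time = 0,
      icu_out_time = los,
      los_hours = los,
      age = round(runif(n, 18, 90)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      care_unit = sample(c("medical", "surgical", "cardiothoracic surgical"),
                         n, replace = TRUE,
                         prob = c(0.6 * (1 - config$cardiothoracic_fraction),
                                  0.4 * (1 - config$cardiothoracic_fraction),
                                  config$cardiothoracic_fraction)),
      elective_surgical = runif(n) < config$elective_fraction,
      pre_icu_antibiotics = runif(n) < config$pre_icu_abx_fraction,
      pre_icu_hours = round(runif(n, 0, 48), 1),
      ever_ventilated = FALSE
    )
    septic_flag <- seq_len(n) %in% septic_ids

    obs_list <- vector("list", n)
    dose_list <- vector("list", n)
    cult_list <- vector("list", n)
    gt_list <- vector("list", n)

    for (i in seq_len(n)) {
      sid <- stays$stay_id[i]
      L <- los[i]
      septic <- septic_flag[i]

      tau <- lag <- NA_real_
      if (septic) {
        tau <- draw_dist(config$infection_time_dist, 1) * L
        tau <- min(max(tau, 2), max(2, L - 20))
        lag <- max(0, draw_dist(config$organ_lag_dist, 1))
      }

      # --- sampled measurements -------------------------------------------
      base_z <- rnorm(nrow(sampled_vars))
      ob <- sampled_vars[, {
        n_obs <- stats::rpois(.N, rate * L)
        list(n_obs = n_obs)
      }, by = variable][sampled_vars, on = "variable"]
      rows <- lapply(seq_len(nrow(ob)), function(v) {
        k <- ob$n_obs[v]
        if (k == 0L) return(NULL)
        tms <- sort(runif(k, 0, L))
        keep <- runif(k) >= config$missingness[[ob$variable[v]]]
        tms <- tms[keep]
        if (!length(tms)) return(NULL)
        vals <- ob$baseline_mean[v] + ob$baseline_sd[v] * base_z[v] +
          rnorm(length(tms), 0, ob$noise_sd[v])
        data.table(variable = ob$variable[v], time = tms, value = vals)
      })
      obs <- rbindlist(rows)

      # --- ventilation / vasopressor state streams ------------------------
      vent_s <- numeric(); vent_e <- numeric()
      if (runif(1) < config$ever_vent_fraction) {
        v0 <- runif(1, 0, L * 0.5)
        vent_s <- c(vent_s, v0); vent_e <- c(vent_e, v0 + runif(1, 12, 72))
      }
      if (septic && runif(1) < config$vent_fraction_septic) {
        d0 <- tau + lag + 2
        if (d0 < L) { vent_s <- c(vent_s, d0); vent_e <- c(vent_e, d0 + 72) }
      }
      vent_obs <- episodes_to_obs(vent_s, vent_e, L)
      if (nrow(vent_obs)) {
        stays$ever_ventilated[i] <- TRUE
        obs <- rbind(obs, data.table(variable = "vent", time = vent_obs$time,
                                     value = vent_obs$value))
      }
      if (septic && runif(1) < config$pressor_fraction_septic) {
        p0 <- tau + lag + 2
        if (p0 < L) {
          p1 <- min(p0 + 48, L - 1e-6)
          if (runif(1) < 0.2) {
            obs <- rbind(obs, data.table(variable = "dopamine",
                                         time = c(p0, p1),
                                         value = c(runif(1, 5, 15), 0)))
          } else {
            obs <- rbind(obs, data.table(variable = "norepinephrine",
                                         time = c(p0, p1),
                                         value = c(runif(1, 0.08, 0.25), 0)))
          }
        }
      }

      # --- deterioration drift --------------------------------------------
      if (septic && nrow(obs)) {
        delta <- inject_sepsis_trajectory(obs, stays[i], tau, config, lag)
        obs[, value := value + delta]
      }
      if (nrow(obs)) {
        obs <- defs[, .(variable, lower, upper)][obs, on = "variable"]
        obs[, value := pmin(pmax(value, lower), upper)]
        obs[variable == "gcs", value := round(pmin(pmax(value, 3), 15))]
        obs[, c("lower", "upper") := NULL]
        obs[, stay_id := sid]
        data.table::setcolorder(obs, c("stay_id", "variable", "time", "value"))
      }
      obs_list[[i]] <- obs

      # --- infection-linked events ----------------------------------------
      doses <- data.table(stay_id = character(), drug_name = character(),
                          time = numeric())
      cults <- data.table(stay_id = character(), specimen_type = character(),
                          time = numeric())
      t_first_abx <- t_first_cult <- NA_real_
      if (septic) {
        k <- draw_dist(config$n_doses_dist, 1)
        first_abx <- tau + draw_dist(config$abx_offset_dist, 1)
        first_abx <- min(max(first_abx, 0.5), L - 1)
        gaps <- draw_dist(config$dose_gap_dist, max(k - 1, 0))
        tms <- first_abx + c(0, cumsum(gaps))
        tms <- tms[tms <= L - 0.25]
        drug <- sample(ABX_POOL, 1)
        doses <- rbind(doses, data.table(stay_id = sid, drug_name = drug, time = tms))
        if (runif(1) < 0.4 && first_abx + 1 < L - 1) {
          t2 <- first_abx + runif(1, 0.5, 12)
          if (t2 <= L - 0.25)
            doses <- rbind(doses, data.table(stay_id = sid,
                                             drug_name = sample(setdiff(ABX_POOL, drug), 1),
                                             time = t2))
        }
        t_first_abx <- min(doses$time)

        t_cult <- tau + draw_dist(config$culture_offset_dist, 1)
        t_cult <- min(max(t_cult, 0.25), L - 0.5)
        spec_type <- if (runif(1) < config$specimen_mix) "blood" else "other"
        cults <- rbind(cults, data.table(stay_id = sid, specimen_type = spec_type,
                                         time = t_cult))
        if (runif(1) < 0.3) {
          t_extra <- runif(1, min(tau, L - 0.5), L - 0.25)
          cults <- rbind(cults, data.table(
            stay_id = sid,
            specimen_type = if (runif(1) < config$specimen_mix) "blood" else "other",
            time = t_extra))
        }
        t_first_cult <- t_cult
      }

      # --- background events (never rule-qualifying) ----------------------
      if (runif(1) < config$background_event_rate) {
        doses <- rbind(doses, data.table(stay_id = sid,
                                         drug_name = sample(ABX_POOL, 1),
                                         time = runif(1, 1, max(1.5, L - 1))))
      }
      if (runif(1) < config$background_event_rate) {
        cults <- rbind(cults, data.table(
          stay_id = sid,
          specimen_type = if (runif(1) < config$specimen_mix) "blood" else "other",
          time = runif(1, 1, max(1.5, L - 1))))
      }
      dose_list[[i]] <- doses
      cult_list[[i]] <- cults

      gt_list[[i]] <- data.table(
        stay_id = sid, is_septic = septic,
        tau_infection = tau,
        true_first_abx = t_first_abx,
        true_first_culture = t_first_cult,
        true_organ_deterioration_time = if (septic) tau + lag else NA_real_
      )
    }

    cohort <- list(
      stays = stays,
      observations = rbindlist(obs_list),
      dose_events = rbindlist(dose_list),
      culture_events = rbindlist(cult_list),
      ground_truth = rbindlist(gt_list),
      config = config
    )
    class(cohort) <- "slab_cohort"
    cohort
  })
}

#' @export
print.slab_cohort <- function(x, ...) {
  cat("<synthetic ICU cohort>\n")
  cat(sprintf("  %d stays (%d septic), %d observations, %d antibiotic doses, %d cultures\n",
              nrow(x$stays), sum(x$ground_truth$is_septic),
              nrow(x$observations), nrow(x$dose_events), nrow(x$culture_events)))
  invisible(x)
}

#' Write a cohort's five tables to disk
#'
#' Writes `stays`, `observations`, `dose_events`, `culture_events` and
#' `ground_truth` as CSV (always) and Parquet (when the arrow package is
#' available), plus a `manifest.json` recording the generator configuration
#' and seed.
#'
#' @param cohort A `slab_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param parquet Also write Parquet copies if arrow is installed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, parquet = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("stays", "observations", "dose_events", "culture_events", "ground_truth")
  for (tb in tabs) {
    data.table::fwrite(cohort[[tb]], file.path(dir, paste0(tb, ".csv")))
    if (parquet && requireNamespace("arrow", quietly = TRUE))
      arrow::write_parquet(cohort[[tb]], file.path(dir, paste0(tb, ".parquet")))
  }
  cfg <- cohort$config
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(list(config = strip(cfg), seed = cfg$seed %||% NA),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing the CSV tables.
#' @return A `slab_cohort` list (without the original config object).
#' @export
read_cohort <- function(dir) {
  tabs <- c("stays", "observations", "dose_events", "culture_events", "ground_truth")
  out <- lapply(tabs, function(tb) data.table::fread(file.path(dir, paste0(tb, ".csv"))))
  names(out) <- tabs
  out$config <- NULL
  class(out) <- "slab_cohort"
  out
}
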