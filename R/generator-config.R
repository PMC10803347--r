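#' Distribution specification helpers
#'
#' Small tagged-list distributions used by [cohort_config()] so that every
#' stochastic choice in the generator is an explicit, serialisable object.
#' `dist_uniform(min, max)`, `dist_normal(mean, sd)`, `dist_constant(value)`
#' and `dist_discrete(values, prob)` are supported.
#'
#' @param min,max,mean,sd,value,values,prob Distribution parameters.
#' @return A list with class `slab_dist`.
#' @name distributions
NULL

#' @rdname distributions
#' @export
dist_uniform <- function(min, max) {
  if (!is.numeric(min) || !is.numeric(max) || max < min)
    stopf("dist_uniform: need numeric min <= max")
  structure(list(kind = "uniform", min = min, max = max), class = "slab_dist")
}

#' @rdname distributions
#' @export
dist_normal <- function(mean, sd) {
  if (!is.numeric(sd) || sd < 0) stopf("dist_normal: sd must be >= 0")
  structure(list(kind = "normal", mean = mean, sd = sd), class = "slab_dist")
}

#' @rdname distributions
#' @export
dist_constant <- function(value) {
  structure(list(kind = "constant", value = value), class = "slab_dist")
}

#' @rdname distributions
#' @export
dist_discrete <- function(values, prob = NULL) {
  if (length(values) < 1L) stopf("dist_discrete: empty support")
  structure(list(kind = "discrete", values = values, prob = prob),
            class = "slab_dist")
}

draw_dist <- function(dist, n) {
  switch(dist$kind,
    uniform  = runif(n, dist$min, dist$max),
    normal   = rnorm(n, dist$mean, dist$sd),
    constant = rep(dist$value, n),
    discrete = {
      idx <- sample.int(length(dist$values), n, replace = TRUE, prob = dist$prob)
      dist$values[idx]
    },
    stopf("unknown distribution kind '%s'", dist$kind)
  )
}

#' Configuration for the synthetic ICU cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' septic fraction, length-of-stay range, the latent infection-time process,
#' the placement of antibiotic courses and culture draws around the latent
#' infection time tau, the lag from tau to physiological deterioration, the
#' per-variable deterioration effect sizes, sampling rates and dropout, and
#' the blood/other specimen mix.
#'
#' Time is measured in hours since ICU admission throughout. Offsets of the
#' first antibiotic dose and first culture draw are signed hours relative to
#' tau; the defaults place both shortly after tau so that the antibiotic /
#' culture proximity pairing rules (24 h / 72 h) are satisfied for almost
#' every septic stay, while `background_event_rate` gives non-septic stays
#' occasional one-off antibiotic doses and stand-alone culture draws that
#' exercise the pairing rules' rejection paths.
#'
#' @param n_patients Number of patients (one ICU stay each).
#' @param septic_fraction Proportion of patients given a latent infection.
#' @param seed Integer seed; identical config + seed reproduces the tables.
#' @param los_range_hours Length-of-stay range (min, max) in hours.
#' @param infection_time_dist Distribution of tau as a fraction of the stay
#'   (drawn in (0, 1), then scaled; clipped so events fit inside the stay).
#' @param abx_offset_dist,culture_offset_dist Signed hour offsets of the
#'   first antibiotic dose / first culture draw relative to tau.
#' @param n_doses_dist,dose_gap_dist Antibiotic course shape: number of
#'   doses and inter-dose gap (hours).
#' @param organ_lag_dist Lag (hours) from tau to the start of organ
#'   dysfunction (the SOFA-relevant variables).
#' @param ramp_hours Hours over which the organ-dysfunction drift ramps
#'   from 0 to its full magnitude.
#' @param prodrome_ramp_hours Hours over which the inflammatory prodrome
#'   (heart rate, respiratory rate, temperature, SpO2, white cells,
#'   lactate) ramps, starting at tau itself; the clinician-response offsets
#'   default to trailing this visible prodrome.
#' @param drift_magnitudes Named numeric vector of per-variable effect
#'   sizes; defaults to the `drift` column of [variable_definitions()].
#' @param sampling_rates Named numeric vector of mean measurements/hour;
#'   defaults to the `rate` column of [variable_definitions()].
#' @param missingness Named numeric vector of per-variable dropout
#'   proportions applied to sampled observation times (default 0.05 for all).
#' @param specimen_mix Proportion of culture draws that are blood cultures.
#' @param background_event_rate Probability that a non-septic stay receives
#'   a one-off antibiotic dose, and independently a stand-alone culture.
#' @param vent_fraction_septic Proportion of septic stays ventilated after
#'   deterioration onset.
#' @param ever_vent_fraction Background proportion of stays with a
#'   ventilation episode unrelated to sepsis.
#' @param pressor_fraction_septic Proportion of septic stays started on a
#'   vasopressor after deterioration onset.
#' @param cardiothoracic_fraction,elective_fraction,pre_icu_abx_fraction
#'   Stay-metadata fractions feeding the exclusion rules.
#'
#' @return An object of class `slab_generator_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 100,
                          septic_fraction = 0.3,
                          seed = 1L,
                          los_range_hours = c(24, 240),
                          infection_time_dist = dist_uniform(0.15, 0.55),
                          abx_offset_dist = dist_normal(8, 2),
                          culture_offset_dist = dist_normal(7, 2),
                          n_doses_dist = dist_discrete(3:6),
                          dose_gap_dist = dist_uniform(6, 12),
                          organ_lag_dist = dist_uniform(4, 10),
                          ramp_hours = 8,
                          prodrome_ramp_hours = 12,
                          drift_magnitudes = NULL,
                          sampling_rates = NULL,
                          missingness = NULL,
                          specimen_mix = 0.9,
                          background_event_rate = 0.15,
                          vent_fraction_septic = 0.7,
                          ever_vent_fraction = 0.2,
                          pressor_fraction_septic = 0.6,
                          cardiothoracic_fraction = 0.05,
                          elective_fraction = 0.08,
                          pre_icu_abx_fraction = 0.05) {
  defs <- variable_definitions()
  if (!is_count(n_patients))
    stopf("invalid configuration: n_patients must be a positive integer")
  if (!is.numeric(septic_fraction) || length(septic_fraction) != 1L ||
      is.na(septic_fraction) || septic_fraction < 0 || septic_fraction > 1)
    stopf("invalid configuration: septic_fraction must lie in [0, 1]")
  if (length(los_range_hours) != 2L || any(los_range_hours <= 0) ||
      los_range_hours[2] < los_range_hours[1])
    stopf("invalid configuration: los_range_hours must be positive (min, max)")
  for (p in c("specimen_mix", "background_event_rate", "vent_fraction_septic",
              "ever_vent_fraction", "pressor_fraction_septic",
              "cardiothoracic_fraction", "elective_fraction",
              "pre_icu_abx_fraction")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1)
      stopf("invalid configuration: %s must lie in [0, 1]", p)
  }
  if (!is.numeric(ramp_hours) || ramp_hours <= 0)
    stopf("invalid configuration: ramp_hours must be > 0")
  if (!is.numeric(prodrome_ramp_hours) || prodrome_ramp_hours <= 0)
    stopf("invalid configuration: prodrome_ramp_hours must be > 0")

  dm <- setNames(defs$drift, defs$variable)
  if (!is.null(drift_magnitudes)) {
    bad <- setdiff(names(drift_magnitudes), defs$variable)
    if (length(bad)) stopf("invalid configuration: unknown variable(s) in drift_magnitudes: %s",
                           paste(bad, collapse = ", "))
    dm[names(drift_magnitudes)] <- drift_magnitudes
  }
  sr <- setNames(defs$rate, defs$variable)
  if (!is.null(sampling_rates)) {
    bad <- setdiff(names(sampling_rates), defs$variable)
    if (length(bad)) stopf("invalid configuration: unknown variable(s) in sampling_rates: %s",
                           paste(bad, collapse = ", "))
    if (any(sampling_rates < 0))
      stopf("invalid configuration: sampling_rates must be >= 0")
    sr[names(sampling_rates)] <- sampling_rates
  }
  ms <- setNames(rep(0.05, nrow(defs)), defs$variable)
  if (!is.null(missingness)) {
    bad <- setdiff(names(missingness), defs$variable)
    if (length(bad)) stopf("invalid configuration: unknown variable(s) in missingness: %s",
                           paste(bad, collapse = ", "))
    if (any(missingness < 0 | missingness > 1))
      stopf("invalid configuration: missingness must lie in [0, 1]")
    ms[names(missingness)] <- missingness
  }
  structure(list(
    n_patients = as.integer(n_patients),
    septic_fraction = septic_fraction,
    seed = as.integer(seed),
    los_range_hours = as.numeric(los_range_hours),
    infection_time_dist = infection_time_dist,
    abx_offset_dist = abx_offset_dist,
    culture_offset_dist = culture_offset_dist,
    n_doses_dist = n_doses_dist,
    dose_gap_dist = dose_gap_dist,
    organ_lag_dist = organ_lag_dist,
    ramp_hours = ramp_hours,
    prodrome_ramp_hours = prodrome_ramp_hours,
    drift_magnitudes = dm,
    sampling_rates = sr,
    missingness = ms,
    specimen_mix = specimen_mix,
    background_event_rate = background_event_rate,
    vent_fraction_septic = vent_fraction_septic,
    ever_vent_fraction = ever_vent_fraction,
    pressor_fraction_septic = pressor_fraction_septic,
    cardiothoracic_fraction = cardiothoracic_fraction,
    elective_fraction = elective_fraction,
    pre_icu_abx_fraction = pre_icu_abx_fraction
  ), class = "slab_generator_config")
}

#' @export
print.slab_generator_config <- function(x, ...) {
  cat("<synthetic ICU cohort configuration>\n")
  cat(sprintf("  patients: %d (septic fraction %.2f), seed %d\n",
              x$n_patients, x$septic_fraction, x$seed))
  cat(sprintf("  length of stay: %.0f-%.0f h; specimen mix (blood): %.2f\n",
              x$los_range_hours[1], x$los_range_hours[2], x$specimen_mix))
  invisible(x)
}
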