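#' Clinical variable vocabulary
#'
#' The fixed vocabulary of raw time-varying clinical variables used by the
#' synthetic generator, the hourly grid and the SOFA engine. It covers
#' everything needed for full six-component SOFA computation (PaO2, FiO2,
#' ventilation flag, platelets, bilirubin, mean arterial pressure,
#' vasopressor doses, Glasgow coma scale, creatinine, urine output) plus the
#' common ICU vitals and chemistry panel.
#'
#' Columns: `variable`, `baseline_mean`, `baseline_sd` (between-patient),
#' `noise_sd` (within-patient), `rate` (mean measurements per hour),
#' `lower`/`upper` (physiological bounds used for clipping and validation)
#' and `drift` (default deterioration effect size for septic patients; sign
#' encodes direction, e.g. platelets fall while bilirubin rises).
#'
#' @return A `data.table` with one row per variable.
#' @export
variable_definitions <- function() {
  dt <- data.table::rbindlist(list(
    # variable            mean    sd    noise  rate    lower upper  drift
    list("heart_rate",      80,   10,   4,     1,       20,  220,   35),
    list("sbp",            120,   12,   6,     1,       40,  260,  -35),
    list("dbp",             70,    8,   4,     1,       20,  160,  -18),
    list("map",             85,    8,   4,     1,       30,  200,  -30),
    list("resp_rate",       16,    3,   1.5,   1,        4,   60,   12),
    list("temp",            36.8,  0.3, 0.2,   0.5,     32,   43,    1.8),
    list("spo2",            97,    1.2, 0.8,   1,       50,  100,   -7),
    list("fio2",             0.21, 0.02,0.01,  0.5,      0.21, 1,    0.30),
    list("pao2",            95,    8,   5,     1/6,     30,  500,  -45),
    list("gcs",             15,    0,   0.3,   0.25,     3,   15,   -6),
    list("platelets",      220,   40,  10,     1/12,     1, 1000, -130),
    list("bilirubin",        0.8,  0.2, 0.1,   1/12,     0.05, 40,   3.5),
    list("creatinine",       0.9,  0.2, 0.1,   1/12,     0.2, 20,    2.2),
    list("lactate",          1.2,  0.3, 0.2,   1/12,     0.3, 25,    2.5),
    list("wbc",              8,    2,   0.8,   1/12,     0.5, 80,    8),
    list("hemoglobin",      12,    1.2, 0.4,   1/12,     4,   22,   -1.5),
    list("hematocrit",      36,    3,   1,     1/12,    12,   65,   -4),
    list("bun",             16,    4,   1.5,   1/12,     2,  150,   12),
    list("glucose",        115,   20,  10,     1/12,    30,  800,   25),
    list("sodium",         139,    2.5, 1,     1/12,   110,  175,    2),
    list("potassium",        4.1,  0.35,0.15,  1/12,     1.5,  9,    0.4),
    list("chloride",       103,    3,   1,     1/12,    75,  130,    2),
    list("bicarbonate",     24,    2,   1,     1/12,     5,   45,   -6),
    list("ph",               7.40, 0.03,0.02,  1/12,     6.8,  7.8, -0.12),
    list("magnesium",        2.0,  0.2, 0.1,   1/24,     0.5,  5,    0.2),
    list("calcium",          9.2,  0.4, 0.2,   1/24,     4,   14,   -0.6),
    list("phosphate",        3.5,  0.5, 0.25,  1/24,     0.5, 12,    1),
    list("albumin",          3.8,  0.4, 0.15,  1/24,     1,    6,   -0.8),
    list("ptt",             32,    4,   2,     1/24,    15,  150,   15),
    list("inr",              1.1,  0.1, 0.05,  1/24,     0.5, 12,    0.5),
    list("urine_output",    70,   12,  10,     1,        0, 1000,  -45),
    list("vent",             0,    0,   0,     0,        0,    1,    0),
    list("dopamine",         0,    0,   0,     0,        0,   50,    0),
    list("norepinephrine",   0,    0,   0,     0,        0,    5,    0)
  ))
  data.table::setnames(dt, c("variable", "baseline_mean", "baseline_sd",
                             "noise_sd", "rate", "lower", "upper", "drift"))
  dt[]
}

# variables whose presence counts as "vital sign data" for exclusion rules
VITAL_VARIABLES <- c("heart_rate", "sbp", "dbp", "map", "resp_rate",
                     "temp", "spo2")

# variables carried as event streams with state semantics (forward-filled
# flags/doses), not sampled measurements
STATE_VARIABLES <- c("vent", "dopamine", "norepinephrine")
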