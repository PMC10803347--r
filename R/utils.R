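#' @import data.table
#' @importFrom stats approx predict quantile rbinom rnorm runif setNames
#'   plogis qlogis sd rexp
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "stay_id", "patient_id", "variable", "time", "value",
  "hour", "drug_name", "course_id", "start_time", "t_abx", "t_cult",
  "t_suspicion", "t_sofa", "t_sepsis", "label", "specimen_type", "total",
  "icu_in_time", "icu_out_time", "los_hours", "split", "included",
  "exclusion_reason", "gap", "qualifies", "n_doses", "is_septic",
  "tau_infection", "score", "alert", "stratum", "age", "sex",
  "ever_ventilated", "pre_icu_hours", "urine_24h", "pf_ratio", "vent",
  "event", "stop_h", "start_h"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# deterministic child seed from a parent seed and a stage label (< 2^31)
child_seed <- function(seed, label) {
  h <- sum(as.integer(charToRaw(label)) * seq_along(charToRaw(label)))
  (as.integer(seed) %% 1000003L) * 1009L + h %% 99991L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss) > 0L)
    stopf("%s is missing required column(s): %s", what, paste(miss, collapse = ", "))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f)
  unname(tools::md5sum(f))
}
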