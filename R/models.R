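#' Fit a patient-hour risk scorer
#'
#' Fits one of the three interchangeable real-time sepsis risk models on a
#' patient-hour feature matrix and label table:
#'
#' * `"gbm"` -- a gradient-boosted tree binary classifier (xgboost,
#'   histogram method, single thread for reproducibility);
#' * `"lstm"` -- a small single-layer LSTM over each stay's hourly feature
#'   sequence with a per-hour sigmoid output (see [fit_lstm_core()]);
#' * `"coxphm"` -- a proportional-hazards model with time-varying
#'   covariates on counting-process patient-hours, scored as the T-hour
#'   event risk `1 - exp(-(H0(t+T) - H0(t)) exp(beta x_t))` with a
#'   Breslow-type baseline cumulative hazard.
#'
#' All three return scores increasing in the likelihood of sepsis onset
#' within the prediction horizon; scoring never reads labels.
#'
#' @param kind One of `"gbm"`, `"lstm"`, `"coxphm"`.
#' @param features `data.table` (`stay_id`, `hour`, feature columns).
#' @param labels `data.table` (`stay_id`, `hour`, `label`).
#' @param horizon Prediction horizon T in hours.
#' @param onsets For `"coxphm"`: table (`stay_id`, `t_sepsis`) giving the
#'   (possibly `NA`) onset per stay; required.
#' @param params Named list of hyperparameters (per-kind defaults applied).
#' @param seed Integer seed controlling fit-time randomness.
#' @return An object of class `slab_scorer` (and a kind subclass) with a
#'   [predict()] method returning one score per feature row.
#' @export
fit_risk_model <- function(kind = c("gbm", "lstm", "coxphm"), features, labels,
                           horizon = 6, onsets = NULL, params = list(),
                           seed = 1L) {
  kind <- match.arg(kind)
  d <- merge_features_labels(features, labels)
  cols <- setdiff(names(features), c("stay_id", "hour"))
  switch(kind,
    gbm = fit_gbm(d, cols, params, seed, horizon),
    lstm = fit_lstm(d, cols, params, seed, horizon),
    coxphm = fit_coxphm(d, cols, params, seed, horizon, onsets))
}

merge_features_labels <- function(features, labels) {
  d <- merge(data.table::as.data.table(features),
             data.table::as.data.table(labels)[, .(stay_id, hour, label)],
             by = c("stay_id", "hour"))
  if (nrow(d) == 0L) stopf("features and labels share no (stay_id, hour) rows")
  data.table::setorder(d, stay_id, hour)
  d
}

new_scorer <- function(kind, fields) {
  structure(c(list(kind = kind), fields),
            class = c(paste0("slab_scorer_", kind), "slab_scorer"))
}

#' @export
print.slab_scorer <- function(x, ...) {
  cat(sprintf("<%s patient-hour risk scorer; %d features; horizon %s h>\n",
              x$kind, length(x$feature_cols), format(x$horizon)))
  invisible(x)
}

# ---- gradient boosted trees ----------------------------------------------

fit_gbm <- function(d, cols, params, seed, horizon) {
  p <- utils::modifyList(list(eta = 0.1, max_depth = 3, nrounds = 100,
                              min_child_weight = 10), params)
  X <- as.matrix(d[, cols, with = FALSE])
  y <- d$label
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  base_score <- min(max(mean(y), 1e-6), 1 - 1e-6)  # degenerate-label safe
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = p$eta,
                  base_score = base_score,
                  max_depth = p$max_depth, min_child_weight = p$min_child_weight,
                  subsample = 1, colsample_bytree = 1, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0)
  new_scorer("gbm", list(booster = booster, feature_cols = cols,
                         params = p, horizon = horizon, seed = seed))
}

#' @export
predict.slab_scorer_gbm <- function(object, newdata, ...) {
  X <- as.matrix(data.table::as.data.table(newdata)[, object$feature_cols,
                                                    with = FALSE])
  predict(object$booster, xgboost::xgb.DMatrix(X))
}

# ---- proportional hazards horizon risk -----------------------------------

fit_coxphm <- function(d, cols, params, seed, horizon, onsets) {
  if (is.null(onsets))
    stopf("coxphm requires the onset table (stay_id, t_sepsis)")
  p <- utils::modifyList(list(lambda = 0.03, alpha = 0), params)
  ons <- data.table::as.data.table(onsets)
  assert_columns(ons, c("stay_id", "t_sepsis"), "onsets")
  d <- merge(d, ons[, .(stay_id, t_sepsis = floor(t_sepsis))],
             by = "stay_id", all.x = TRUE)
  X <- as.matrix(d[, cols, with = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- is.finite(scl) & scl > 1e-10
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  event <- as.integer(!is.na(d$t_sepsis) & d$hour + 1 == d$t_sepsis)
  if (sum(event) == 0L) stopf("coxphm: no onset events in the training data")
  y <- survival::Surv(d$hour, d$hour + 1, event)
  # ridge-penalised partial likelihood keeps the fit finite when the
  # covariates are collinear or nearly separate the event rows; escalate
  # the penalty if the solver still diverges
  beta <- NULL
  lam <- p$lambda
  for (try_i in 1:4) {
    fit <- tryCatch(suppressWarnings(
      glmnet::glmnet(Xs, y, family = "cox", alpha = p$alpha,
                     lambda = lam, standardize = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      b <- as.numeric(fit$beta[, 1])
      if (all(is.finite(b))) { beta <- b; break }
    }
    lam <- lam * 5
  }
  if (is.null(beta))
    stopf("coxphm fit diverged (alpha=%g, lambda up to %g)", p$alpha, lam)
  lp <- as.vector(Xs %*% beta)
  # Breslow baseline cumulative hazard on the unit intervals (h, h+1]:
  # the risk set at event time s is exactly the rows with hour == s - 1
  risk <- data.table(hour = d$hour, e = event, w = exp(lp))
  denom <- risk[, .(denom = sum(w), d_events = sum(e)), by = hour]
  denom <- denom[d_events > 0]
  data.table::setorder(denom, hour)
  baseline <- data.frame(time = denom$hour + 1,
                         cumhaz = cumsum(denom$d_events / denom$denom))
  new_scorer("coxphm", list(
    beta = beta, center = ctr[keep], scale = scl[keep],
    kept_cols = cols[keep], feature_cols = cols,
    baseline = baseline,
    horizon = horizon, params = p, seed = seed))
}

# Linearly interpolated Breslow cumulative hazard, anchored at (0, 0) and
# extrapolated past the last event time at the average observed rate, so
# every horizon increment H0(t+T) - H0(t) is strictly positive.
cumhaz_at <- function(baseline, t) {
  if (nrow(baseline) == 0L) return(rep(0, length(t)))
  tt <- c(0, baseline$time)
  hh <- c(0, baseline$cumhaz)
  n <- length(tt)
  rate <- hh[n] / max(tt[n], 1)
  tt <- c(tt, tt[n] + 1e6)
  hh <- c(hh, hh[n] + 1e6 * rate)
  approx(tt, hh, xout = pmax(t, 0), method = "linear", rule = 2)$y
}

#' @export
predict.slab_scorer_coxphm <- function(object, newdata, ...) {
  nd <- data.table::as.data.table(newdata)
  X <- as.matrix(nd[, object$kept_cols, with = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  lp <- as.vector(Xs %*% object$beta)
  h <- nd$hour
  dH <- cumhaz_at(object$baseline, h + object$horizon) -
    cumhaz_at(object$baseline, h)
  1 - exp(-dH * exp(lp))
}

# ---- lstm ----------------------------------------------------------------

fit_lstm <- function(d, cols, params, seed, horizon) {
  p <- utils::modifyList(list(hidden = 16L, epochs = 15L, lr = 0.01,
                              pos_weight = 1), params)
  X <- as.matrix(d[, cols, with = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl < 1e-10] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  net <- fit_lstm_core(Xs, d$label, d$stay_id, hidden = p$hidden,
                       epochs = p$epochs, lr = p$lr,
                       pos_weight = p$pos_weight, seed = seed)
  new_scorer("lstm", list(net = net, center = ctr, scale = scl,
                          feature_cols = cols, params = p,
                          horizon = horizon, seed = seed))
}

#' @export
predict.slab_scorer_lstm <- function(object, newdata, ...) {
  nd <- data.table::as.data.table(newdata)
  X <- as.matrix(nd[, object$feature_cols, with = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  predict_lstm_core(object$net, Xs, nd$stay_id, nd$hour)
}

# ---- threshold calibration & binarization --------------------------------

#' Calibrate the alert threshold to a target training sensitivity
#'
#' Returns the largest threshold whose patient-hour sensitivity on the
#' supplied (training) scores is at least the target: with `P` positive
#' rows, the threshold is the `ceiling(target * P)`-th highest positive
#' score.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels aligned with `scores`.
#' @param target Target sensitivity (default 0.85).
#' @return List of class `slab_threshold` with `threshold`,
#'   `achieved_sensitivity` and `target`.
#' @export
calibrate_threshold <- function(scores, labels, target = 0.85) {
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  pos <- scores[labels == 1]
  if (length(pos) == 0L) stopf("cannot calibrate a threshold without positive labels")
  k <- ceiling(target * length(pos))
  thr <- sort(pos, decreasing = TRUE)[k]
  structure(list(threshold = thr,
                 achieved_sensitivity = mean(pos >= thr),
                 target = target),
            class = "slab_threshold")
}

#' Convert a risk trace to binary alerts
#'
#' Flags every patient-hour whose score is at or above the threshold and
#' reports the first alert hour (per stay if `stay_id` is present).
#'
#' @param risk_trace `data.table`/data.frame with `score` and `hour`
#'   columns (optionally `stay_id`).
#' @param threshold Alert threshold (a number or a `slab_threshold`).
#' @return List with `trace` (input plus logical `alert`) and
#'   `first_alert` (`data.table` of first alert hours; `NA` if no alert).
#' @export
binarize <- function(risk_trace, threshold) {
  if (inherits(threshold, "slab_threshold")) threshold <- threshold$threshold
  if (!is.finite(threshold)) stopf("threshold must be finite")
  tr <- data.table::as.data.table(risk_trace)
  assert_columns(tr, c("hour", "score"), "risk_trace")
  tr[, alert := score >= threshold]
  fa <- if ("stay_id" %in% names(tr)) {
    tr[, .(first_alert = if (any(alert)) min(hour[alert]) else NA_real_),
       by = stay_id]
  } else {
    data.table(first_alert = if (any(tr$alert)) min(tr$hour[tr$alert]) else NA_real_)
  }
  list(trace = tr[], first_alert = fa[])
}

# ---- grouped cross-validated tuning --------------------------------------

#' Tune hyperparameters with patient-grouped k-fold cross-validation
#'
#' Folds partition patients, so no patient contributes rows to two folds.
#' Each grid row is scored by the mean patient-hour AUROC across folds; the
#' best row is refitted on the full training data.
#'
#' @param kind Model kind (see [fit_risk_model()]).
#' @param features,labels Patient-hour tables as in [fit_risk_model()].
#' @param param_grid `data.frame` of hyperparameter combinations (one row
#'   per configuration).
#' @param k Number of folds (default 5).
#' @param horizon,onsets,seed Passed to [fit_risk_model()].
#' @return List with `best_params` (named list), `cv_table` (fold x config
#'   AUROCs) and `scorer` (refit on all data).
#' @export
tune_cv <- function(kind, features, labels, param_grid, k = 5,
                    horizon = 6, onsets = NULL, seed = 1L) {
  param_grid <- as.data.frame(param_grid)
  if (nrow(param_grid) == 0L) stopf("param_grid must be non-empty")
  stays <- sort(unique(features$stay_id))
  if (length(stays) < k)
    stopf("fewer distinct patients (%d) than folds (%d)", length(stays), k)
  fold <- with_seed(child_seed(seed, "cv_folds"),
                    sample(rep(seq_len(k), length.out = length(stays))))
  names(fold) <- stays
  cv_rows <- list()
  for (ci in seq_len(nrow(param_grid))) {
    pars <- as.list(param_grid[ci, , drop = FALSE])
    for (fi in seq_len(k)) {
      tr_ids <- stays[fold != fi]
      va_ids <- stays[fold == fi]
      sc <- fit_risk_model(kind,
                           features[features$stay_id %in% tr_ids, ],
                           labels[labels$stay_id %in% tr_ids, ],
                           horizon = horizon,
                           onsets = onsets, params = pars, seed = seed)
      va_f <- merge_features_labels(features[features$stay_id %in% va_ids, ],
                                    labels[labels$stay_id %in% va_ids, ])
      au <- auroc(predict(sc, va_f), va_f$label)
      cv_rows[[length(cv_rows) + 1L]] <-
        data.table(config = ci, fold = fi, auroc = au)
    }
  }
  cv_table <- rbindlist(cv_rows)
  mean_au <- cv_table[, .(mean_auroc = mean(auroc, na.rm = TRUE)), by = config]
  best <- mean_au$config[which.max(mean_au$mean_auroc)]
  best_params <- as.list(param_grid[best, , drop = FALSE])
  scorer <- fit_risk_model(kind, features, labels, horizon = horizon,
                           onsets = onsets, params = best_params, seed = seed)
  list(best_params = best_params, cv_table = cv_table[], scorer = scorer,
       fold_assignment = fold)
}
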