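sigmoid <- function(x) 1 / (1 + exp(-x))

# Pack patient-hour rows into padded per-stay sequences.
# Returns idx[n_stays, max_len] of row indices into X (NA = padding).
pack_sequences <- function(stay_ids, hours) {
  dt <- data.table(row = seq_along(stay_ids), sid = stay_ids, hour = hours)
  data.table::setorder(dt, sid, hour)
  dt[, pos := seq_len(.N), by = sid]
  sids <- unique(dt$sid)
  max_len <- max(dt$pos)
  idx <- matrix(NA_integer_, nrow = length(sids), ncol = max_len,
                dimnames = list(sids, NULL))
  idx[cbind(match(dt$sid, sids), dt$pos)] <- dt$row
  idx
}

init_lstm_params <- function(p, H, seed) {
  with_seed(seed, {
    sc_x <- sqrt(6 / (p + H)); sc_h <- sqrt(6 / (2 * H))
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    list(Wx = matrix(runif(p * 4 * H, -sc_x, sc_x), p, 4 * H),
         Wh = matrix(runif(H * 4 * H, -sc_h, sc_h), H, 4 * H),
         b = b,
         Wo = matrix(runif(H, -sc_h, sc_h), H, 1),
         bo = 0)
  })
}

lstm_forward <- function(par, X, idx, keep_cache = FALSE) {
  H <- ncol(par$Wh)
  H1 <- H / 4
  n_seq <- nrow(idx); T_max <- ncol(idx)
  XW <- X %*% par$Wx  # precompute input projections for all rows
  Hs <- matrix(0, n_seq, H1); Cs <- matrix(0, n_seq, H1)
  yhat <- numeric(nrow(X))
  cache <- if (keep_cache) vector("list", T_max) else NULL
  for (t in seq_len(T_max)) {
    rows <- idx[, t]
    live <- which(!is.na(rows))
    if (!length(live)) next
    Zi <- XW[rows[live], , drop = FALSE] +
      Hs[live, , drop = FALSE] %*% par$Wh +
      matrix(par$b, length(live), H, byrow = TRUE)
    ig <- sigmoid(Zi[, 1:H1, drop = FALSE])
    fg <- sigmoid(Zi[, (H1 + 1):(2 * H1), drop = FALSE])
    gg <- tanh(Zi[, (2 * H1 + 1):(3 * H1), drop = FALSE])
    og <- sigmoid(Zi[, (3 * H1 + 1):(4 * H1), drop = FALSE])
    Cprev <- Cs[live, , drop = FALSE]
    Cnew <- fg * Cprev + ig * gg
    tC <- tanh(Cnew)
    Hnew <- og * tC
    y_t <- sigmoid(Hnew %*% par$Wo + par$bo)
    yhat[rows[live]] <- y_t
    if (keep_cache)
      cache[[t]] <- list(live = live, rows = rows[live], i = ig, f = fg,
                         g = gg, o = og, Cprev = Cprev, C = Cnew, tC = tC,
                         Hprev = Hs[live, , drop = FALSE], Hnew = Hnew)
    Hs[live, ] <- Hnew
    Cs[live, ] <- Cnew
  }
  list(yhat = yhat, cache = cache)
}

#' Fit the core LSTM sequence scorer
#'
#' A single-layer LSTM with a per-timestep sigmoid read-out, trained with
#' backpropagation through time and Adam on the masked (per-patient-hour)
#' binary cross-entropy, using mini-batches of whole stays. Written in
#' vectorised base R; runs single-threaded, so a fixed seed gives
#' reproducible fits.
#'
#' @param X Standardised feature matrix (rows = patient-hours).
#' @param y 0/1 labels per row.
#' @param stay_ids Stay identifier per row (defines the sequences).
#' @param hidden Hidden state width.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_stays Stays per mini-batch.
#' @param pos_weight Weight on positive rows in the loss.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return A list of trained parameters plus the training loss trace.
#' @export
fit_lstm_core <- function(X, y, stay_ids, hidden = 16L, epochs = 15L,
                          lr = 0.01, batch_stays = 64L, pos_weight = 1,
                          seed = 1L) {
  p <- ncol(X)
  idx <- pack_sequences(stay_ids, seq_along(stay_ids))  # order as given
  n_seq <- nrow(idx)
  par <- init_lstm_params(p, hidden, seed)
  mom <- lapply(par, function(w) w * 0)
  vel <- lapply(par, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  w_all <- ifelse(y == 1, pos_weight, 1)
  losses <- numeric(epochs)
  step <- 0L
  with_seed(child_seed(seed, "lstm_batches"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_seq)
      batches <- split(ord, ceiling(seq_along(ord) / batch_stays))
      ep_loss <- 0
      for (bt in batches) {
        idx_b <- idx[bt, , drop = FALSE]
        rows_b <- sort(idx_b[!is.na(idx_b)])
        Xb <- X[rows_b, , drop = FALSE]
        yb <- y[rows_b]
        idx_rb <- matrix(match(idx_b, rows_b), nrow = nrow(idx_b))
        keep_t <- colSums(!is.na(idx_rb)) > 0
        idx_rb <- idx_rb[, keep_t, drop = FALSE]
        w_row <- w_all[rows_b] / sum(w_all[rows_b])
        fw <- lstm_forward(par, Xb, idx_rb, keep_cache = TRUE)
        yh <- pmin(pmax(fw$yhat, 1e-8), 1 - 1e-8)
        ep_loss <- ep_loss -
          sum(w_row * (yb * log(yh) + (1 - yb) * log(1 - yh)))
        if (!is.finite(ep_loss))
          stopf("non-finite LSTM training loss at epoch %d", ep)
        grad <- lstm_backward(par, Xb, idx_rb, fw, yb, w_row)
        step <- step + 1L
        for (nm in names(par)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * grad[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * grad[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[ep] <- ep_loss
    }
  })
  c(par, list(hidden = hidden, loss_trace = losses))
}

lstm_backward <- function(par, X, idx, fw, y, w_row) {
  H1 <- ncol(par$Wh) / 4
  T_max <- ncol(idx); n_seq <- nrow(idx)
  gWx <- par$Wx * 0; gWh <- par$Wh * 0; gb <- par$b * 0
  gWo <- par$Wo * 0; gbo <- 0
  dH_next <- matrix(0, n_seq, H1); dC_next <- matrix(0, n_seq, H1)
  yh <- pmin(pmax(fw$yhat, 1e-8), 1 - 1e-8)
  dy_all <- w_row * (yh - y)  # d(loss)/d(pre-sigmoid output)
  for (t in rev(seq_len(T_max))) {
    cc <- fw$cache[[t]]
    if (is.null(cc)) next
    live <- cc$live
    dy <- dy_all[cc$rows]
    dH <- dH_next[live, , drop = FALSE] + outer(dy, as.vector(par$Wo))
    gWo <- gWo + t(cc$Hnew) %*% matrix(dy, ncol = 1)
    gbo <- gbo + sum(dy)
    dC <- dC_next[live, , drop = FALSE] + dH * cc$o * (1 - cc$tC^2)
    d_o <- dH * cc$tC * cc$o * (1 - cc$o)
    d_i <- dC * cc$g * cc$i * (1 - cc$i)
    d_f <- dC * cc$Cprev * cc$f * (1 - cc$f)
    d_g <- dC * cc$i * (1 - cc$g^2)
    dZ <- cbind(d_i, d_f, d_g, d_o)
    Xt <- X[cc$rows, , drop = FALSE]
    gWx <- gWx + t(Xt) %*% dZ
    gWh <- gWh + t(cc$Hprev) %*% dZ
    gb <- gb + colSums(dZ)
    dH_prev <- dZ %*% t(par$Wh)
    dC_prev <- dC * cc$f
    dH_next[live, ] <- dH_prev
    dC_next[live, ] <- dC_prev
    # sequences not live at t keep their accumulated gradients
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wo = gWo, bo = gbo)
}

#' Score patient-hours with a fitted core LSTM
#' @param net Output of [fit_lstm_core()].
#' @param X Standardised feature matrix.
#' @param stay_ids,hours Row keys defining sequence order.
#' @return Numeric risk score per row.
#' @export
predict_lstm_core <- function(net, X, stay_ids, hours) {
  idx <- pack_sequences(stay_ids, hours)
  lstm_forward(net, X, idx, keep_cache = FALSE)$yhat
}
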