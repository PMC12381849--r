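# Minimal neural-network engine: dense, 1D convolution + max-pooling,
# simple-recurrent and LSTM layers with full backpropagation, softmax
# cross-entropy loss, and the optimizer families used for tuning. All
# parameters live in flat named lists of arrays so optimizers are
# generic.
#
# Sequence tensors are stored stacked: a (batch*T) x channels matrix
# whose rows (t-1)*batch + 1 .. t*batch hold timestep t. Input-side
# matrix products then run once over all timesteps; only the recurrent
# state update loops over t. A (batch x T) mask freezes state updates
# past each sample's true length, so padding never influences recurrent
# outputs.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) pmax(x, 0)

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.t_rows <- function(t, nb) ((t - 1L) * nb + 1L):(t * nb)

# ---- dense -----------------------------------------------------------

.dense_init <- function(nin, nout) list(W = .glorot(nin, nout),
                                        b = numeric(nout))

.dense_fwd <- function(p, X, act = c("relu", "linear")) {
  act <- match.arg(act)
  Z <- X %*% p$W + rep(p$b, each = nrow(X))
  A <- if (act == "relu") .relu(Z) else Z
  list(A = A, cache = list(X = X, Z = Z, act = act))
}

.dense_bwd <- function(p, cache, dA) {
  dZ <- if (cache$act == "relu") dA * (cache$Z > 0) else dA
  list(dW = crossprod(cache$X, dZ), db = colSums(dZ),
       dX = tcrossprod(dZ, p$W))
}

# ---- 1D convolution (same padding) and max pooling -------------------

.conv1d_init <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * cin + cout))
  W <- lapply(seq_len(k), function(i)
    matrix(stats::runif(cin * cout, -lim, lim), cin, cout))
  list(W = W, b = numeric(cout), k = k)
}

.conv1d_fwd <- function(p, Xs, nb) {
  Tn <- nrow(Xs) / nb
  k <- p$k; pad <- (k - 1L) %/% 2L
  Z <- matrix(rep(p$b, each = nrow(Xs)), nrow(Xs))
  for (dk in seq_len(k)) {
    sh <- dk - 1L - pad                   # out t draws from t + sh
    t_lo <- max(1L, 1L - sh); t_hi <- min(Tn, Tn - sh)
    if (t_lo > t_hi) next
    orows <- ((t_lo - 1L) * nb + 1L):(t_hi * nb)
    srows <- orows + sh * nb
    Z[orows, ] <- Z[orows, , drop = FALSE] +
      Xs[srows, , drop = FALSE] %*% p$W[[dk]]
  }
  list(A = .relu(Z), cache = list(Xs = Xs, Z = Z, nb = nb, Tn = Tn))
}

.conv1d_bwd <- function(p, cache, dA, need_dX = TRUE) {
  nb <- cache$nb; Tn <- cache$Tn
  k <- p$k; pad <- (k - 1L) %/% 2L
  dZ <- dA * (cache$Z > 0)
  dW <- vector("list", k)
  dX <- if (need_dX) cache$Xs * 0 else NULL
  for (dk in seq_len(k)) {
    sh <- dk - 1L - pad
    t_lo <- max(1L, 1L - sh); t_hi <- min(Tn, Tn - sh)
    if (t_lo > t_hi) { dW[[dk]] <- p$W[[dk]] * 0; next }
    orows <- ((t_lo - 1L) * nb + 1L):(t_hi * nb)
    srows <- orows + sh * nb
    dW[[dk]] <- crossprod(cache$Xs[srows, , drop = FALSE],
                          dZ[orows, , drop = FALSE])
    if (need_dX)
      dX[srows, ] <- dX[srows, , drop = FALSE] +
        tcrossprod(dZ[orows, , drop = FALSE], p$W[[dk]])
  }
  list(dW = dW, db = colSums(dZ), dX = dX)
}

.maxpool_fwd <- function(Xs, nb, size = 2L) {
  Tn <- nrow(Xs) / nb
  To <- as.integer(ceiling(Tn / size))
  A <- matrix(-Inf, To * nb, ncol(Xs))
  src <- matrix(0L, To * nb, ncol(Xs))
  for (u in seq_len(To)) {
    orows <- .t_rows(u, nb)
    cur <- A[orows, , drop = FALSE]
    cs <- src[orows, , drop = FALSE]
    for (t in ((u - 1L) * size + 1L):min(u * size, Tn)) {
      blk <- Xs[.t_rows(t, nb), , drop = FALSE]
      upd <- blk > cur
      cur[upd] <- blk[upd]
      cs[upd] <- t
    }
    A[orows, ] <- cur
    src[orows, ] <- cs
  }
  list(A = A, cache = list(src = src, Tn = Tn, nb = nb))
}

.maxpool_bwd <- function(cache, dA) {
  nb <- cache$nb
  dX <- matrix(0, cache$Tn * nb, ncol(dA))
  To <- nrow(dA) / nb
  for (u in seq_len(To)) {
    orows <- .t_rows(u, nb)
    su <- cache$src[orows, , drop = FALSE]
    du <- dA[orows, , drop = FALSE]
    for (t in unique(as.vector(su))) {
      if (t == 0L) next
      hit <- su == t
      srows <- .t_rows(t, nb)
      tmp <- dX[srows, , drop = FALSE]
      tmp[hit] <- tmp[hit] + du[hit]
      dX[srows, ] <- tmp
    }
  }
  dX
}

# ---- simple RNN ------------------------------------------------------

.rnn_init <- function(nin, units) {
  list(Wx = .glorot(nin, units), Wh = .glorot(units, units),
       b = numeric(units))
}

.rnn_fwd <- function(p, Xs, mask, nb, reverse = FALSE) {
  Tn <- nrow(Xs) / nb; U <- nrow(p$Wh)
  ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  XW <- Xs %*% p$Wx + rep(p$b, each = nrow(Xs))
  h <- matrix(0, nb, U)
  Hs <- matrix(0, Tn * nb, U)
  cache <- vector("list", Tn)
  for (t in ts) {
    m <- mask[, t]
    hn <- tanh(XW[.t_rows(t, nb), , drop = FALSE] + h %*% p$Wh)
    cache[[t]] <- list(h_prev = h, hn = hn, m = m)
    h <- if (all(m == 1)) hn else m * hn + (1 - m) * h
    Hs[.t_rows(t, nb), ] <- h
  }
  list(Hs = Hs, final = h, cache = cache, ts = ts, nb = nb, Xs = Xs)
}

.rnn_bwd <- function(p, fwd, dHs, dfinal = NULL, need_dX = TRUE) {
  ts <- fwd$ts; nb <- fwd$nb
  dWh <- p$Wh * 0
  dZ <- matrix(0, nrow(fwd$Xs), ncol(p$Wh))
  dh <- if (is.null(dfinal)) fwd$final * 0 else dfinal
  for (t in rev(ts)) {
    cc <- fwd$cache[[t]]
    rows <- .t_rows(t, nb)
    dht <- dh + (if (is.null(dHs)) 0 else dHs[rows, , drop = FALSE])
    dhn <- cc$m * dht
    dz <- dhn * (1 - cc$hn^2)
    dZ[rows, ] <- dz
    dWh <- dWh + crossprod(cc$h_prev, dz)
    dh <- (1 - cc$m) * dht + tcrossprod(dz, p$Wh)
  }
  list(dWx = crossprod(fwd$Xs, dZ), dWh = dWh, db = colSums(dZ),
       dX = if (need_dX) tcrossprod(dZ, p$Wx) else NULL)
}

# ---- LSTM ------------------------------------------------------------

.lstm_init <- function(nin, units) {
  p <- list(Wx = .glorot(nin, 4L * units),
            Wh = .glorot(units, 4L * units),
            b = numeric(4L * units))
  p$b[(units + 1L):(2L * units)] <- 1  # forget-gate bias
  p
}

# gate column layout: [i | f | o] sigmoid block, then [g] tanh block
.lstm_fwd <- function(p, Xs, mask, nb, reverse = FALSE) {
  Tn <- nrow(Xs) / nb; U <- nrow(p$Wh)
  ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  XW <- Xs %*% p$Wx + rep(p$b, each = nrow(Xs))
  h <- matrix(0, nb, U); cmem <- matrix(0, nb, U)
  Hs <- matrix(0, Tn * nb, U)
  cache <- vector("list", Tn)
  i_ix <- 1:U; f_ix <- (U + 1L):(2L * U); o_ix <- (2L * U + 1L):(3L * U)
  g_ix <- (3L * U + 1L):(4L * U)
  for (t in ts) {
    m <- mask[, t]
    full <- all(m == 1)
    A <- XW[.t_rows(t, nb), , drop = FALSE] + h %*% p$Wh
    S <- .sigmoid(A[, 1L:(3L * U), drop = FALSE])
    gi <- S[, i_ix, drop = FALSE]
    gf <- S[, f_ix, drop = FALSE]
    go <- S[, o_ix, drop = FALSE]
    gg <- tanh(A[, g_ix, drop = FALSE])
    cn <- gf * cmem + gi * gg
    tc <- tanh(cn)
    hn <- go * tc
    cache[[t]] <- list(h_prev = h, c_prev = cmem, gi = gi, gf = gf,
                       gg = gg, go = go, tc = tc, m = m, full = full)
    if (full) {
      h <- hn; cmem <- cn
    } else {
      h <- m * hn + (1 - m) * h
      cmem <- m * cn + (1 - m) * cmem
    }
    Hs[.t_rows(t, nb), ] <- h
  }
  list(Hs = Hs, final = h, cache = cache, ts = ts, nb = nb, U = U,
       Xs = Xs)
}

.lstm_bwd <- function(p, fwd, dHs, dfinal = NULL, need_dX = TRUE) {
  ts <- fwd$ts; U <- fwd$U; nb <- fwd$nb
  dWh <- p$Wh * 0
  dAs <- matrix(0, nrow(fwd$Xs), 4L * U)
  dh <- if (is.null(dfinal)) fwd$final * 0 else dfinal
  dc <- dh * 0
  for (t in rev(ts)) {
    cc <- fwd$cache[[t]]
    rows <- .t_rows(t, nb)
    dht <- dh + (if (is.null(dHs)) 0 else dHs[rows, , drop = FALSE])
    if (cc$full) {
      dhn <- dht
      dct <- dc + dhn * cc$go * (1 - cc$tc^2)
      dcn <- dct
      dh_prev0 <- 0
      dc_carry <- dcn * cc$gf
    } else {
      dhn <- cc$m * dht
      dh_prev0 <- (1 - cc$m) * dht
      dct <- dc + dhn * cc$go * (1 - cc$tc^2)
      dcn <- cc$m * dct
      dc_carry <- (1 - cc$m) * dct + dcn * cc$gf
    }
    dA <- cbind((dcn * cc$gg) * cc$gi * (1 - cc$gi),
                (dcn * cc$c_prev) * cc$gf * (1 - cc$gf),
                (dhn * cc$tc) * cc$go * (1 - cc$go),
                (dcn * cc$gi) * (1 - cc$gg^2))
    dAs[rows, ] <- dA
    dWh <- dWh + crossprod(cc$h_prev, dA)
    dh <- dh_prev0 + tcrossprod(dA, p$Wh)
    dc <- dc_carry
  }
  list(dWx = crossprod(fwd$Xs, dAs), dWh = dWh, db = colSums(dAs),
       dX = if (need_dX) tcrossprod(dAs, p$Wx) else NULL)
}

# bidirectional wrapper: concat forward and backward unit activations;
# forward final = state at each sample's last valid step (mask freezes),
# backward final = state after sweeping back to t = 1
.bilstm_fwd <- function(pf, pb, Xs, mask, nb, cell = c("lstm", "rnn")) {
  cell <- match.arg(cell)
  fwd_fn <- if (cell == "lstm") .lstm_fwd else .rnn_fwd
  fwd <- fwd_fn(pf, Xs, mask, nb)
  bwd <- fwd_fn(pb, Xs, mask, nb, reverse = TRUE)
  list(Hs = cbind(fwd$Hs, bwd$Hs), final = cbind(fwd$final, bwd$final),
       fwd = fwd, bwd = bwd, cell = cell)
}

.bilstm_bwd <- function(pf, pb, run, dHs, dfinal = NULL,
                        need_dX = TRUE) {
  U <- ncol(run$fwd$final)
  dH_f <- if (is.null(dHs)) NULL else dHs[, 1:U, drop = FALSE]
  dH_b <- if (is.null(dHs)) NULL else dHs[, (U + 1L):(2L * U),
                                          drop = FALSE]
  dff <- if (is.null(dfinal)) NULL else dfinal[, 1:U, drop = FALSE]
  dfb <- if (is.null(dfinal)) NULL else dfinal[, (U + 1L):(2L * U),
                                               drop = FALSE]
  bwd_fn <- if (run$cell == "lstm") .lstm_bwd else .rnn_bwd
  gf <- bwd_fn(pf, run$fwd, dH_f, dff, need_dX)
  gb <- bwd_fn(pb, run$bwd, dH_b, dfb, need_dX)
  list(f = gf, b = gb,
       dX = if (need_dX) gf$dX + gb$dX else NULL)
}

# ---- loss ------------------------------------------------------------

.softmax_ce <- function(logits, onehot) {
  probs <- .softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(rowSums(onehot * log(probs + eps)))
  list(probs = probs, loss = loss,
       dlogits = (probs - onehot) / nrow(logits))
}

# ---- optimizers ------------------------------------------------------

# state and updates operate on flat lists of arrays; `grads` must be
# positionally aligned with `params`
.opt_init <- function(optimizer, params, lr = NULL, momentum = NULL) {
  zeros <- lapply(params, function(p) p * 0)
  defaults <- c(sgd = 0.01, adagrad = 0.01, adadelta = 1.0,
                rmsprop = 0.001, adam = 0.001, adamax = 0.002,
                nadam = 0.001)
  if (is.null(lr)) lr <- unname(defaults[optimizer])
  list(optimizer = optimizer, lr = lr, t = 0L,
       momentum = if (is.null(momentum)) 0.9 else momentum,
       m = zeros, v = zeros, u = zeros)
}

.opt_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  lr <- st$lr
  b1 <- st$momentum; b2 <- 0.999; eps <- 1e-8
  for (k in seq_along(params)) {
    g <- grads[[k]]
    switch(st$optimizer,
      sgd = {
        st$m[[k]] <- st$momentum * st$m[[k]] - lr * g
        params[[k]] <- params[[k]] + st$m[[k]]
      },
      adagrad = {
        st$v[[k]] <- st$v[[k]] + g^2
        params[[k]] <- params[[k]] - lr * g / (sqrt(st$v[[k]]) + eps)
      },
      adadelta = {
        rho <- 0.95
        st$v[[k]] <- rho * st$v[[k]] + (1 - rho) * g^2
        upd <- -sqrt(st$u[[k]] + eps) / sqrt(st$v[[k]] + eps) * g
        st$u[[k]] <- rho * st$u[[k]] + (1 - rho) * upd^2
        params[[k]] <- params[[k]] + lr * upd
      },
      rmsprop = {
        rho <- 0.9
        st$v[[k]] <- rho * st$v[[k]] + (1 - rho) * g^2
        params[[k]] <- params[[k]] - lr * g / (sqrt(st$v[[k]]) + eps)
      },
      adam = {
        st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
        st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
        mh <- st$m[[k]] / (1 - b1^st$t)
        vh <- st$v[[k]] / (1 - b2^st$t)
        params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
      },
      adamax = {
        st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
        st$u[[k]] <- pmax(b2 * st$u[[k]], abs(g))
        params[[k]] <- params[[k]] -
          lr / (1 - b1^st$t) * st$m[[k]] / (st$u[[k]] + eps)
      },
      nadam = {
        st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
        st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
        mh <- st$m[[k]] / (1 - b1^st$t)
        vh <- st$v[[k]] / (1 - b2^st$t)
        params[[k]] <- params[[k]] -
          lr * (b1 * mh + (1 - b1) * g / (1 - b1^st$t)) /
            (sqrt(vh) + eps)
      },
      stop("unknown optimizer: ", st$optimizer))
  }
  list(state = st, params = params)
}

.optimizer_names <- function() c("sgd", "adadelta", "adagrad", "rmsprop",
                                 "adam", "adamax", "nadam")
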