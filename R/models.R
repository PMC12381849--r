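#' Model specification
#'
#' Architecture and training hyperparameters for the three classifier
#' families. `mlp_lstm` feeds the variable-length shift sequence through
#' two stacked bidirectional LSTM layers (50 units per direction; forward
#' and backward final states concatenated to 100) into two dense layers,
#' concatenates the fixed per-signal input at the 500-node layer, and
#' finishes with a dense stack and an m-way softmax. `mlp_rnn` is the
#' same wiring with simple tanh recurrent cells. `cnn` runs the
#' zero-padded sequence through convolution/max-pooling blocks (pool
#' divisor 2: a length-N input leaves ceiling(N/2)), flattens,
#' concatenates the fixed input and finishes with a dense stack.
#'
#' @param architecture one of `"mlp_lstm"`, `"cnn"`, `"mlp_rnn"`.
#' @param m number of output classes (>= 2).
#' @param recurrent_units hidden states per direction (default 50).
#' @param seq_dense dense widths after the recurrent branch; the last is
#'   the concatenation point (default `c(250, 500)`).
#' @param fixed_dense width of the fixed-input branch (default 64).
#' @param head_dense width of the post-concatenation layer (default 100).
#' @param conv_filters filters per convolution block (default
#'   `c(32, 64)`).
#' @param kernel convolution kernel size (default 3).
#' @param pool_divisor max-pool window (default 2).
#' @param cnn_dense dense width after flattening (default 128).
#' @param epochs training epochs (default 120, inside the 100--150 window
#'   where validation accuracy plateaus).
#' @param batch_size minibatch size (default 64).
#' @param optimizer one of sgd, adadelta, adagrad, rmsprop, adam, adamax,
#'   nadam (default adam with library-default rate).
#' @param lr learning rate; `NULL` uses the optimizer family default.
#' @param momentum momentum / first-moment coefficient; `NULL` uses 0.9.
#' @param seed RNG seed controlling initialization and batch order.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("mlp_lstm", "cnn", "mlp_rnn"),
                       m, recurrent_units = 50L,
                       seq_dense = c(250L, 500L), fixed_dense = 64L,
                       head_dense = 100L, conv_filters = c(32L, 64L),
                       kernel = 3L, pool_divisor = 2L, cnn_dense = 128L,
                       epochs = 120L, batch_size = 64L,
                       optimizer = "adam", lr = NULL, momentum = NULL,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  if (m < 2L) stop("need at least 2 output classes")
  if (!optimizer %in% .optimizer_names())
    stop("unknown optimizer '", optimizer, "'")
  structure(list(architecture = architecture, m = as.integer(m),
                 recurrent_units = as.integer(recurrent_units),
                 seq_dense = as.integer(seq_dense),
                 fixed_dense = as.integer(fixed_dense),
                 head_dense = as.integer(head_dense),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 pool_divisor = as.integer(pool_divisor),
                 cnn_dense = as.integer(cnn_dense),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer, lr = lr, momentum = momentum,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# parameter construction ------------------------------------------------

.init_params <- function(spec, p_fixed, seq_len, seq_channels = 2L) {
  U <- spec$recurrent_units
  p <- list()
  if (spec$architecture %in% c("mlp_lstm", "mlp_rnn")) {
    cell_init <- if (spec$architecture == "mlp_lstm") .lstm_init
                 else .rnn_init
    p$l1f <- cell_init(seq_channels, U)
    p$l1b <- cell_init(seq_channels, U)
    p$l2f <- cell_init(2L * U, U)
    p$l2b <- cell_init(2L * U, U)
    p$d1 <- .dense_init(2L * U, spec$seq_dense[1])
    p$d2 <- .dense_init(spec$seq_dense[1], spec$seq_dense[2])
    p$fx <- .dense_init(p_fixed, spec$fixed_dense)
    p$h1 <- .dense_init(spec$seq_dense[2] + spec$fixed_dense,
                        spec$head_dense)
    p$out <- .dense_init(spec$head_dense, spec$m)
  } else {
    f <- spec$conv_filters
    p$c1 <- .conv1d_init(spec$kernel, seq_channels, f[1])
    len <- ceiling(seq_len / spec$pool_divisor)
    p$c2 <- .conv1d_init(spec$kernel, f[1], f[2])
    len <- ceiling(len / spec$pool_divisor)
    p$cf <- .dense_init(p_fixed, spec$fixed_dense)
    p$fl <- .dense_init(len * f[2] + spec$fixed_dense, spec$cnn_dense)
    p$out <- .dense_init(spec$cnn_dense, spec$m)
  }
  p
}

.flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    for (sub in names(p[[nm]])) {
      v <- p[[nm]][[sub]]
      if (is.list(v)) {
        for (k in seq_along(v))
          out[[paste(nm, sub, k, sep = ".")]] <- v[[k]]
      } else if (sub != "k") out[[paste(nm, sub, sep = ".")]] <- v
    }
  }
  out
}

.unflatten_params <- function(flat, skeleton) {
  for (nm in names(skeleton)) {
    for (sub in names(skeleton[[nm]])) {
      v <- skeleton[[nm]][[sub]]
      if (is.list(v)) {
        for (k in seq_along(v))
          skeleton[[nm]][[sub]][[k]] <- flat[[paste(nm, sub, k,
                                                    sep = ".")]]
      } else if (sub != "k")
        skeleton[[nm]][[sub]] <- flat[[paste(nm, sub, sep = ".")]]
    }
  }
  skeleton
}

# forward/backward per architecture -------------------------------------

.forward <- function(p, spec, batch) {
  if (spec$architecture %in% c("mlp_lstm", "mlp_rnn")) {
    cell <- if (spec$architecture == "mlp_lstm") "lstm" else "rnn"
    nb <- nrow(batch$fixed)
    r1 <- .bilstm_fwd(p$l1f, p$l1b, batch$Xs, batch$mask, nb, cell)
    r2 <- .bilstm_fwd(p$l2f, p$l2b, r1$Hs, batch$mask, nb, cell)
    d1 <- .dense_fwd(p$d1, r2$final, "relu")
    d2 <- .dense_fwd(p$d2, d1$A, "relu")
    fx <- .dense_fwd(p$fx, batch$fixed, "relu")
    cat_in <- cbind(d2$A, fx$A)
    h1 <- .dense_fwd(p$h1, cat_in, "relu")
    out <- .dense_fwd(p$out, h1$A, "linear")
    list(logits = out$A,
         cache = list(r1 = r1, r2 = r2, d1 = d1, d2 = d2, fx = fx,
                      h1 = h1, out = out, cat_dim = ncol(d2$A)))
  } else {
    nb <- nrow(batch$fixed)
    c1 <- .conv1d_fwd(p$c1, batch$Xs, nb)
    p1 <- .maxpool_fwd(c1$A, nb, spec$pool_divisor)
    c2 <- .conv1d_fwd(p$c2, p1$A, nb)
    p2 <- .maxpool_fwd(c2$A, nb, spec$pool_divisor)
    flat <- p2$A                    # (nb*To) x F -> nb x (To*F):
    dim(flat) <- c(nb, length(p2$A) / nb)  # same data layout, no copy
    cf <- .dense_fwd(p$cf, batch$fixed, "relu")
    fl_in <- cbind(flat, cf$A)
    fl <- .dense_fwd(p$fl, fl_in, "relu")
    out <- .dense_fwd(p$out, fl$A, "linear")
    list(logits = out$A,
         cache = list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, cf = cf,
                      fl = fl, out = out, flat_dim = ncol(flat),
                      pool_rows = nrow(p2$A), pool_f = ncol(p2$A)))
  }
}

.backward <- function(p, spec, batch, fw, dlogits) {
  g <- list()
  ch <- fw$cache
  if (spec$architecture %in% c("mlp_lstm", "mlp_rnn")) {
    b_out <- .dense_bwd(p$out, ch$out$cache, dlogits)
    b_h1 <- .dense_bwd(p$h1, ch$h1$cache, b_out$dX)
    dcat <- b_h1$dX
    dd2 <- dcat[, seq_len(ch$cat_dim), drop = FALSE]
    dfx <- dcat[, -seq_len(ch$cat_dim), drop = FALSE]
    b_fx <- .dense_bwd(p$fx, ch$fx$cache, dfx)
    b_d2 <- .dense_bwd(p$d2, ch$d2$cache, dd2)
    b_d1 <- .dense_bwd(p$d1, ch$d1$cache, b_d2$dX)
    b_r2 <- .bilstm_bwd(p$l2f, p$l2b, ch$r2, NULL, b_d1$dX)
    b_r1 <- .bilstm_bwd(p$l1f, p$l1b, ch$r1, b_r2$dX, NULL,
                        need_dX = FALSE)
    g$l1f <- b_r1$f[c("dWx", "dWh", "db")]
    g$l1b <- b_r1$b[c("dWx", "dWh", "db")]
    g$l2f <- b_r2$f[c("dWx", "dWh", "db")]
    g$l2b <- b_r2$b[c("dWx", "dWh", "db")]
    names(g$l1f) <- names(g$l1b) <- names(g$l2f) <- names(g$l2b) <-
      c("Wx", "Wh", "b")
    g$d1 <- list(W = b_d1$dW, b = b_d1$db)
    g$d2 <- list(W = b_d2$dW, b = b_d2$db)
    g$fx <- list(W = b_fx$dW, b = b_fx$db)
    g$h1 <- list(W = b_h1$dW, b = b_h1$db)
    g$out <- list(W = b_out$dW, b = b_out$db)
  } else {
    b_out <- .dense_bwd(p$out, ch$out$cache, dlogits)
    b_fl <- .dense_bwd(p$fl, ch$fl$cache, b_out$dX)
    dflat <- b_fl$dX[, seq_len(ch$flat_dim), drop = FALSE]
    dcf <- b_fl$dX[, -seq_len(ch$flat_dim), drop = FALSE]
    b_cf <- .dense_bwd(p$cf, ch$cf$cache, dcf)
    dim(dflat) <- c(ch$pool_rows, ch$pool_f)
    dA_c2 <- .maxpool_bwd(ch$p2$cache, dflat)
    b_c2 <- .conv1d_bwd(p$c2, ch$c2$cache, dA_c2)
    dA_c1 <- .maxpool_bwd(ch$p1$cache, b_c2$dX)
    b_c1 <- .conv1d_bwd(p$c1, ch$c1$cache, dA_c1, need_dX = FALSE)
    g$c1 <- list(W = b_c1$dW, b = b_c1$db)
    g$c2 <- list(W = b_c2$dW, b = b_c2$db)
    g$cf <- list(W = b_cf$dW, b = b_cf$db)
    g$fl <- list(W = b_fl$dW, b = b_fl$db)
    g$out <- list(W = b_out$dW, b = b_out$db)
  }
  g
}

# scaling ---------------------------------------------------------------

.fit_scaler <- function(bundle, rows) {
  fx <- bundle$fixed[rows, , drop = FALSE]
  ctr <- colMeans(fx)
  scl <- apply(fx, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  sh <- bundle$fixed[rows, "shift"]
  ssd <- stats::sd(sh)
  if (!is.finite(ssd) || ssd < 1e-8) ssd <- 1
  list(center = ctr, scale = scl,
       shift_mean = mean(sh), shift_sd = ssd)
}

.prepare_batch <- function(bundle, rows, scaler, truncate = FALSE) {
  fx <- sweep(sweep(bundle$fixed[rows, , drop = FALSE], 2,
                    scaler$center, "-"), 2, scaler$scale, "/")
  mask <- bundle$mask[rows, , drop = FALSE]
  ss <- (bundle$seq_shifts[rows, , drop = FALSE] - scaler$shift_mean) /
    scaler$shift_sd * mask       # padded positions stay exactly zero
  sm <- bundle$seq_mult[rows, , drop = FALSE] / 4
  if (truncate) {
    # recurrent nets: drop padded timesteps beyond the batch's longest
    # sequence (masked updates make them exact no-ops)
    Tb <- max(bundle$lengths[rows])
    mask <- mask[, seq_len(Tb), drop = FALSE]
    ss <- ss[, seq_len(Tb), drop = FALSE]
    sm <- sm[, seq_len(Tb), drop = FALSE]
  }
  # stacked sequence tensor: rows (t-1)*nb + 1 .. t*nb hold timestep t
  list(fixed = fx, Xs = cbind(as.vector(ss), as.vector(sm)),
       mask = mask)
}

.onehot <- function(classes, m) {
  oh <- matrix(0, length(classes), m)
  oh[cbind(seq_along(classes), classes + 1L)] <- 1
  oh
}

#' Build an untrained model
#'
#' Initializes the parameter tensors of a [model_spec()] for given input
#' dimensions, using a seeded Glorot scheme.
#'
#' @param spec a [model_spec()].
#' @param p_fixed number of fixed-input columns.
#' @param seq_len padded sequence length.
#' @return An object of class `nss_model` with `fitted = FALSE`.
#' @export
build_model <- function(spec, p_fixed, seq_len) {
  set.seed(spec$seed)
  params <- .init_params(spec, p_fixed, seq_len)
  structure(list(spec = spec, params = params, p_fixed = p_fixed,
                 seq_len = seq_len, scaler = NULL, history = NULL,
                 fitted = FALSE),
            class = "nss_model")
}

#' Number of trainable parameters
#'
#' @param model an `nss_model`.
#' @return Integer total over all weight tensors.
#' @export
n_params <- function(model) {
  sum(vapply(.flatten_params(model$params), length, integer(1)))
}

#' Fit a substructure classifier
#'
#' Trains one of the three architectures on a [featurize_records()]
#' bundle against 0-based class labels, by minibatch gradient descent on
#' the categorical cross-entropy of the softmax output. Inputs are
#' standardized internally on the training rows (padding positions stay
#' zero); the scaler is stored so `predict()` reproduces the layout.
#' Training is deterministic for a fixed seed in single-threaded BLAS.
#'
#' @param features a `feature_bundle`.
#' @param classes integer vector of 0-based class labels, aligned with
#'   the bundle rows.
#' @param m number of classes.
#' @param architecture passed to [model_spec()] unless `spec` is given.
#' @param spec optional complete [model_spec()].
#' @param validation optional list(features, classes) evaluated each
#'   epoch.
#' @param verbose print per-epoch progress.
#' @param ... further arguments to [model_spec()].
#' @return A fitted `nss_model` with a per-epoch `history` data frame
#'   (loss/accuracy for training and, when given, validation data).
#' @examples
#' \donttest{
#' syn <- generate_synthetic(synthetic_config(n_molecules = 30, seed = 1))
#' cfg <- feature_config(syn$records)
#' fb <- featurize_records(syn$records, cfg)
#' vocab <- build_vocabulary(syn$truth$label_obj)
#' cls <- labels_to_classes(syn$truth$label_obj, vocab)
#' fit <- nss_fit(fb, cls, m = attr(vocab, "m"), architecture = "cnn",
#'                epochs = 10)
#' head(predict(fit, fb))
#' }
#' @export
nss_fit <- function(features, classes, m, architecture = "mlp_lstm",
                    spec = NULL, validation = NULL, verbose = FALSE,
                    ...) {
  if (is.null(spec)) spec <- model_spec(architecture, m = m, ...)
  classes <- as.integer(classes)
  n <- nrow(features$fixed)
  if (length(classes) != n)
    stop("features (", n, " rows) and classes (", length(classes),
         ") are misaligned")
  if (any(classes < 0L | classes >= spec$m))
    stop("class labels must lie in 0..", spec$m - 1L)
  model <- build_model(spec, ncol(features$fixed), features$config$max_len)
  model$scaler <- .fit_scaler(features, seq_len(n))
  model <- .train_loop(model, features, classes, validation, verbose)
  model
}

#' Train an already-built model
#'
#' The lower-level counterpart of [nss_fit()] for a [build_model()]
#' result; `targets` may be a one-hot matrix or 0-based class vector.
#'
#' @param model an `nss_model`.
#' @param features a `feature_bundle`.
#' @param targets one-hot matrix (n x m) or integer class vector.
#' @inheritParams nss_fit
#' @return The fitted model.
#' @export
train_model <- function(model, features, targets, validation = NULL,
                        verbose = FALSE) {
  classes <- if (is.matrix(targets)) {
    if (any(abs(rowSums(targets) - 1) > 1e-9))
      stop("each one-hot target row must contain exactly one 1")
    max.col(targets, ties.method = "first") - 1L
  } else as.integer(targets)
  n <- nrow(features$fixed)
  if (length(classes) != n)
    stop("features and targets are misaligned")
  model$scaler <- .fit_scaler(features, seq_len(n))
  .train_loop(model, features, classes, validation, verbose)
}

.train_loop <- function(model, features, classes, validation = NULL,
                        verbose = FALSE) {
  spec <- model$spec
  n <- nrow(features$fixed)
  set.seed(spec$seed + 1L)
  flat <- .flatten_params(model$params)
  opt <- .opt_init(spec$optimizer, flat, spec$lr, spec$momentum)
  onehot <- .onehot(classes, spec$m)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     accuracy = numeric(), val_loss = numeric(),
                     val_accuracy = numeric())
  bs <- min(spec$batch_size, n)
  recurrent <- spec$architecture %in% c("mlp_lstm", "mlp_rnn")
  for (ep in seq_len(spec$epochs)) {
    ord <- if (recurrent) {
      # bucket-by-length: group similar lengths so in-batch padding is
      # short; batch order and ties are shuffled each epoch
      sh <- sample.int(n)
      sh[order(features$lengths[sh])]
    } else sample.int(n)
    starts <- seq(1L, n, by = bs)
    if (recurrent) starts <- sample(starts)
    ep_loss <- 0; ep_hit <- 0
    for (start in starts) {
      rows <- ord[start:min(start + bs - 1L, n)]
      batch <- .prepare_batch(features, rows, model$scaler,
                              truncate = recurrent)
      fw <- .forward(model$params, spec, batch)
      ls <- .softmax_ce(fw$logits, onehot[rows, , drop = FALSE])
      if (!is.finite(ls$loss))
        stop("training diverged at epoch ", ep, " (non-finite loss); ",
             "try a smaller learning rate")
      grads <- .backward(model$params, spec, batch, fw, ls$dlogits)
      step <- .opt_step(opt, flat, .flatten_params(grads))
      opt <- step$state; flat <- step$params
      model$params <- .unflatten_params(flat, model$params)
      ep_loss <- ep_loss + ls$loss * length(rows)
      ep_hit <- ep_hit +
        sum(max.col(ls$probs, ties.method = "first") - 1L ==
              classes[rows])
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n,
                      accuracy = ep_hit / n, val_loss = NA_real_,
                      val_accuracy = NA_real_)
    if (!is.null(validation)) {
      vp <- predict(structure(model, fitted = TRUE), validation$features)
      voh <- .onehot(as.integer(validation$classes), spec$m)
      row$val_loss <- -mean(rowSums(voh * log(vp + 1e-12)))
      row$val_accuracy <- mean(max.col(vp, ties.method = "first") - 1L ==
                                 validation$classes)
    }
    hist <- rbind(hist, row)
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f%s\n", ep, row$loss,
                  row$accuracy,
                  if (!is.null(validation))
                    sprintf("  val_acc %.3f", row$val_accuracy) else ""))
  }
  model$history <- hist
  model$fitted <- TRUE
  model
}

#' Predict class probabilities
#'
#' @param object a fitted `nss_model`.
#' @param newdata a `feature_bundle` with the same layout the model was
#'   trained on.
#' @param type `"prob"` for an n x m probability matrix (rows sum to 1),
#'   `"class"` for 0-based argmax labels (ties toward the lowest index).
#' @param ... unused.
#' @return Matrix of probabilities or integer vector.
#' @export
predict.nss_model <- function(object, newdata,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (ncol(newdata$fixed) != object$p_fixed)
    stop("feature layout mismatch: model expects ", object$p_fixed,
         " fixed columns, got ", ncol(newdata$fixed))
  if (newdata$config$max_len != object$seq_len)
    stop("feature layout mismatch: model expects padded length ",
         object$seq_len, ", got ", newdata$config$max_len)
  n <- nrow(newdata$fixed)
  probs <- matrix(NA_real_, n, object$spec$m)
  bs <- 512L
  recurrent <- object$spec$architecture %in% c("mlp_lstm", "mlp_rnn")
  for (start in seq(1L, n, by = bs)) {
    rows <- start:min(start + bs - 1L, n)
    batch <- .prepare_batch(newdata, rows, object$scaler,
                            truncate = recurrent)
    fw <- .forward(object$params, object$spec, batch)
    probs[rows, ] <- .softmax_rows(fw$logits)
  }
  if (type == "class") return(max.col(probs, ties.method = "first") - 1L)
  probs
}

#' @export
print.nss_model <- function(x, ...) {
  cat("<nss_model> ", x$spec$architecture, ", ", x$spec$m, " classes, ",
      n_params(x), " parameters",
      if (x$fitted) " (fitted)" else " (untrained)", "\n", sep = "")
  if (x$fitted) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f, accuracy %.3f (%d epochs)\n",
                last$loss, last$accuracy, nrow(x$history)))
  }
  invisible(x)
}

#' @export
summary.nss_model <- function(object, ...) {
  print(object)
  cat("  optimizer:", object$spec$optimizer,
      " batch:", object$spec$batch_size,
      " seed:", object$spec$seed, "\n")
  if (object$fitted && any(!is.na(object$history$val_accuracy))) {
    best <- which.max(object$history$val_accuracy)
    cat(sprintf("  best validation accuracy %.3f at epoch %d\n",
                object$history$val_accuracy[best], best))
  }
  invisible(object)
}

#' @method plot nss_model
#' @export
plot.nss_model <- function(x, ...) {
  if (!x$fitted) stop("model is not fitted")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = x$spec$architecture)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::plot(h$epoch, h$accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "history")
  if (any(!is.na(h$val_accuracy)))
    graphics::lines(h$epoch, h$val_accuracy, lty = 2)
  invisible(x)
}

# splitting and grid search ---------------------------------------------

#' Train/test split and cross-validation folds
#'
#' `split_train_test()` draws a seeded random 80/20 (by default) split;
#' `cv_folds()` partitions indices into k folds for cross-validation.
#'
#' @param n number of rows.
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed RNG seed.
#' @return `split_train_test()`: list with disjoint `train` and `test`
#'   index vectors covering `1:n`.
#' @export
split_train_test <- function(n, test_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  test <- sort(sample.int(n, round(n * test_fraction)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' @rdname split_train_test
#' @param idx indices to partition.
#' @param k number of folds (default 3).
#' @return `cv_folds()`: list of k disjoint index vectors.
#' @export
cv_folds <- function(idx, k = 3L, seed = 1L) {
  set.seed(seed)
  f <- sample(rep_len(seq_len(k), length(idx)))
  lapply(seq_len(k), function(j) idx[f == j])
}

#' Exhaustive hyperparameter grid search with cross-validation
#'
#' Evaluates every grid point with k-fold cross-validation and returns
#' the configuration with the highest mean validation accuracy; ties go
#' to the smallest batch size, then the fewest epochs. A failing fold
#' marks the combination failed and the search continues.
#'
#' @param features a `feature_bundle` (training split).
#' @param classes 0-based labels aligned with `features`.
#' @param m number of classes.
#' @param architecture architecture name.
#' @param grid named list of hyperparameter vectors (any of
#'   `batch_size`, `epochs`, `optimizer`, `lr`, `momentum`).
#' @param folds number of CV folds (default 3).
#' @param seed RNG seed for folds and model fits.
#' @param ... fixed [model_spec()] arguments shared by all grid points.
#' @return List with `best` (named list of winning hyperparameters),
#'   `best_score`, and `table` (one row per grid point with mean and
#'   per-fold accuracies; failed combinations carry `NA`).
#' @export
grid_search <- function(features, classes, m, architecture, grid,
                        folds = 3L, seed = 1L, ...) {
  stopifnot(length(grid) >= 1L, !is.null(names(grid)))
  tab <- expand.grid(grid, stringsAsFactors = FALSE)
  n <- nrow(features$fixed)
  fold_idx <- cv_folds(seq_len(n), folds, seed)
  scores <- matrix(NA_real_, nrow(tab), folds)
  for (g in seq_len(nrow(tab))) {
    args <- as.list(tab[g, , drop = FALSE])
    for (f in seq_len(folds)) {
      val <- fold_idx[[f]]
      tr <- setdiff(seq_len(n), val)
      res <- tryCatch({
        sp <- do.call(model_spec,
                      c(list(architecture = architecture, m = m,
                             seed = seed), args, list(...)))
        fit <- nss_fit(subset_bundle(features, tr), classes[tr],
                       m = m, spec = sp)
        pred <- predict(fit, subset_bundle(features, val),
                        type = "class")
        mean(pred == classes[val])
      }, error = function(e) {
        warning("grid point ", g, " fold ", f, " failed: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      scores[g, f] <- res
    }
  }
  mean_acc <- rowMeans(scores)
  tab$mean_accuracy <- mean_acc
  for (f in seq_len(folds)) tab[[paste0("fold", f)]] <- scores[, f]
  ok <- which(!is.na(mean_acc))
  if (!length(ok)) stop("every grid point failed")
  key_batch <- if ("batch_size" %in% names(tab)) tab$batch_size[ok]
               else rep(0, length(ok))
  key_epoch <- if ("epochs" %in% names(tab)) tab$epochs[ok]
               else rep(0, length(ok))
  best <- ok[order(-mean_acc[ok], key_batch, key_epoch)][1]
  list(best = as.list(tab[best, names(grid), drop = FALSE]),
       best_score = mean_acc[best], table = tab)
}

#' Subset a feature bundle by row
#'
#' @param bundle a `feature_bundle`.
#' @param rows row indices.
#' @return The row-subset `feature_bundle`.
#' @export
subset_bundle <- function(bundle, rows) {
  structure(list(fixed = bundle$fixed[rows, , drop = FALSE],
                 seq_shifts = bundle$seq_shifts[rows, , drop = FALSE],
                 seq_mult = bundle$seq_mult[rows, , drop = FALSE],
                 mask = bundle$mask[rows, , drop = FALSE],
                 lengths = bundle$lengths[rows],
                 molecule = bundle$molecule[rows],
                 atom_index = bundle$atom_index[rows],
                 config = bundle$config),
            class = "feature_bundle")
}
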