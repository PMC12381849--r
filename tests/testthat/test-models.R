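test_that("analytic gradients match central differences", {
  # smooth coordinates dominate; a few may sit on a ReLU/max-pool kink
  # where the finite difference is invalid, so compare quantiles
  for (arch in c("mlp_lstm", "mlp_rnn", "cnn")) {
    errs <- rel_grad_errors(arch, seed = 42L)
    expect_lt(stats::median(errs), 1e-6)
    expect_gte(mean(errs < 1e-4), 0.9)
  }
})

test_that("model specs validate and count parameters arithmetically", {
  expect_error(model_spec("cnn", m = 1), "at least 2")
  expect_error(model_spec("cnn", m = 3, optimizer = "bogus"),
               "unknown optimizer")
  # hand-computed total for a small recurrent spec:
  U <- 4L; Cin <- 2L; pfix <- 3L
  spec <- model_spec("mlp_lstm", m = 3, recurrent_units = U,
                     seq_dense = c(5L, 6L), fixed_dense = 4L,
                     head_dense = 5L)
  model <- build_model(spec, pfix, 4L)
  lstm1 <- Cin * 4 * U + U * 4 * U + 4 * U       # per direction
  lstm2 <- (2 * U) * 4 * U + U * 4 * U + 4 * U
  dense <- (2 * U) * 5 + 5 + 5 * 6 + 6 +          # d1, d2
    pfix * 4 + 4 +                                # fixed branch
    (6 + 4) * 5 + 5 +                             # head
    5 * 3 + 3                                     # output
  expect_equal(n_params(model), 2 * lstm1 + 2 * lstm2 + dense)
  # cnn flatten width reflects ceiling division by the pool size twice
  for (L in c(7L, 8L, 29L)) {
    cm <- build_model(model_spec("cnn", m = 3, conv_filters = c(3L, 4L),
                                 cnn_dense = 6L, fixed_dense = 5L),
                      pfix, L)
    expect_equal(nrow(cm$params$fl$W),
                 ceiling(ceiling(L / 2) / 2) * 4L + 5L)
  }
})

test_that("shape mismatches fail before training starts", {
  fb <- tiny_bundle()
  expect_error(nss_fit(fb, 0:1, m = 3, architecture = "cnn"),
               "misaligned")
  expect_error(nss_fit(fb, rep(5L, nrow(fb$fixed)), m = 3,
                       architecture = "cnn"),
               "labels must lie")
  expect_error(train_model(build_model(model_spec("cnn", m = 3), 3L, 4L),
                           fb, matrix(0.5, nrow(fb$fixed), 3)),
               "one-hot")
})

test_that("training is reproducible and memorizes tiny data", {
  sb <- separable_bundle(n_per_class = 6L, m = 3L)
  cls <- attr(sb, "classes")
  f1 <- nss_fit(sb, cls, m = 3, architecture = "cnn", epochs = 15,
                conv_filters = c(4L, 4L), cnn_dense = 8L, seed = 5)
  f2 <- nss_fit(sb, cls, m = 3, architecture = "cnn", epochs = 15,
                conv_filters = c(4L, 4L), cnn_dense = 8L, seed = 5)
  expect_identical(f1$params, f2$params)   # bit-reproducible
  expect_identical(f1$history, f2$history)
  # capacity sanity: an easily separable set is fit to high accuracy
  expect_gte(tail(f1$history$accuracy, 1), 0.95)
  # a single example is memorized
  one <- subset_bundle(sb, 1L)
  fo <- nss_fit(one, cls[1], m = 3, architecture = "cnn", epochs = 60,
                conv_filters = c(2L, 2L), cnn_dense = 4L, seed = 1)
  expect_equal(predict(fo, one, type = "class"), cls[1])
})

test_that("zero-noise separable classes train to perfect accuracy", {
  # the nearest-base-shift rule proves 100% is attainable; the nets
  # must reach it within the epoch budget
  sb <- separable_bundle(n_per_class = 15L, m = 5L, seed = 3)
  cls <- attr(sb, "classes")
  for (arch in c("cnn", "mlp_lstm")) {
    fit <- nss_fit(sb, cls, m = 5, architecture = arch, epochs = 80,
                   seed = 2)
    expect_gte(tail(fit$history$accuracy, 1), 0.99)
  }
})

test_that("predictions are probability vectors preserving batch order", {
  sb <- separable_bundle(n_per_class = 5L, m = 3L)
  fit <- nss_fit(sb, attr(sb, "classes"), m = 3, architecture = "cnn",
                 epochs = 5, conv_filters = c(2L, 2L), cnn_dense = 4L,
                 seed = 8)
  p <- predict(fit, sb)
  expect_equal(dim(p), c(nrow(sb$fixed), 3L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-5)
  # order preserved: reversing rows reverses predictions
  rev_idx <- rev(seq_len(nrow(sb$fixed)))
  p_rev <- predict(fit, subset_bundle(sb, rev_idx))
  expect_equal(p_rev, p[rev_idx, ], tolerance = 1e-10)
  # layout mismatches are refused
  bad <- sb
  bad$fixed <- cbind(bad$fixed, extra = 0)
  expect_error(predict(fit, bad), "layout mismatch")
})

test_that("every optimizer family takes a training step", {
  sb <- separable_bundle(n_per_class = 4L, m = 2L)
  cls <- attr(sb, "classes")
  for (opt in c("sgd", "adadelta", "adagrad", "rmsprop", "adam",
                "adamax", "nadam")) {
    fit <- nss_fit(sb, cls, m = 2, architecture = "cnn", epochs = 3,
                   conv_filters = c(2L, 2L), cnn_dense = 4L,
                   optimizer = opt, seed = 4)
    expect_true(all(is.finite(fit$history$loss)))
    expect_false(identical(fit$params,
                           build_model(fit$spec, 3L, 3L)$params))
  }
})

test_that("grid search evaluates exhaustively and breaks ties low", {
  sb <- separable_bundle(n_per_class = 10L, m = 3L, seed = 5)
  cls <- attr(sb, "classes")
  # one-point grid returns that point
  g1 <- grid_search(sb, cls, m = 3, architecture = "cnn",
                    grid = list(batch_size = 16L),
                    folds = 2L, seed = 1, epochs = 5L,
                    conv_filters = c(2L, 2L), cnn_dense = 4L)
  expect_equal(g1$best$batch_size, 16L)
  expect_equal(nrow(g1$table), 1L)
  # the momentum grid enumerates six values
  momenta <- seq(0, 1, by = 0.2)
  expect_length(momenta, 6L)
  # planted best: 1 epoch cannot learn, 40 can
  g2 <- grid_search(sb, cls, m = 3, architecture = "cnn",
                    grid = list(epochs = c(1L, 40L)),
                    folds = 3L, seed = 2,
                    conv_filters = c(2L, 4L), cnn_dense = 8L)
  expect_equal(g2$best$epochs, 40L)
  expect_equal(nrow(g2$table), 2L)
  expect_gte(g2$best_score, max(g2$table$mean_accuracy, na.rm = TRUE))
})

test_that("histories, printing and plotting work on fitted models", {
  sb <- separable_bundle(n_per_class = 4L, m = 2L)
  cls <- attr(sb, "classes")
  val <- list(features = subset_bundle(sb, 1:4), classes = cls[1:4])
  fit <- nss_fit(sb, cls, m = 2, architecture = "cnn", epochs = 4,
                 conv_filters = c(2L, 2L), cnn_dense = 4L,
                 validation = val, seed = 6)
  expect_equal(nrow(fit$history), 4L)
  expect_true(all(!is.na(fit$history$val_accuracy)))
  expect_output(print(fit), "cnn")
  expect_output(summary(fit), "optimizer")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(fit))
  grDevices::dev.off()
})
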