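test_that("tuned configurations match the per-architecture selection table", {
  g <- recommended_config("gru")
  expect_identical(g$spec$n_layers, 3L)
  expect_identical(g$spec$units_per_layer, 10L)
  expect_identical(g$spec$hidden_activation, "Elu")
  expect_identical(g$spec$output_activation, "Linear")
  expect_identical(g$spec$multistep, "encoder_decoder")
  expect_identical(g$spec$window$input_len, 50L)
  expect_identical(g$spec$window$output_len, 1L)
  expect_identical(g$config$optimizer, "Adam")
  expect_identical(g$config$learning_rate, 0.005)
  expect_identical(g$config$epochs, 1000L)
  expect_identical(g$config$batch_size, 200L)
  expect_identical(g$config$loss, "MSE")

  cl <- recommended_config("cnn_lstm")
  expect_identical(cl$spec$n_layers, 1L)
  expect_identical(cl$spec$units_per_layer, 20L)
  expect_identical(cl$spec$hidden_activation, "Tanh")
  expect_identical(cl$spec$output_activation, "Swish")
  expect_identical(cl$config$loss, "MAE")
  expect_identical(cl$config$batch_size, 200L)

  bg <- recommended_config("bi_gru")
  expect_identical(bg$spec$output_activation, "Sigmoid")
  expect_identical(bg$config$learning_rate, 0.003)
  expect_identical(bg$config$epochs, 1000L)

  expect_length(architectures(), 7L)
  expect_error(recommended_config("transformer"), "unknown architecture")
})

test_that("model specs reject inconsistent settings", {
  expect_error(model_spec("gru", 1L, 4L, "Tanh", "Softmax"), "output-layer activation")
  expect_error(model_spec("gru", 0L, 4L, "Tanh", "Linear"), ">= 1")
  expect_error(model_spec("cnn_lstm", 1L, 4L, "Tanh", "Linear",
                          window = window_spec(3L, 1L, 1L)), "at least 4")
  expect_error(model_spec("gru", 1L, 4L, "NotAFunction", "Linear"), "hidden-layer")
})

test_that("builds are deterministic and output shape follows the window spec", {
  spec <- model_spec("lstm", 2L, 4L, "Tanh", "Linear", "vector", window_spec(12L, 3L, 1L))
  m1 <- build_model(spec, seed = 5)
  m2 <- build_model(spec, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, seed = 6)
  expect_false(identical(m1$params, m3$params))

  X <- matrix(rnorm(7 * 12), 7, 12)
  tc <- train_config(epochs = 1L, seed = 5)
  fit <- train_predictor(m1, make_supervised(sin(1:40) / 2 + 0.5, spec$window),
                         config = tc)
  p <- predict(fit, X)
  expect_identical(dim(p), c(7L, 3L))
})

test_that("bidirectional variants have strictly more parameters than unidirectional", {
  for (pair in list(c("simple_rnn", "bi_simple_rnn"), c("lstm", "bi_lstm"),
                    c("gru", "bi_gru"))) {
    w <- window_spec(6L, 1L, 1L)
    uni <- build_model(model_spec(pair[1], 1L, 2L, "Tanh", "Linear", "vector", w))
    bi <- build_model(model_spec(pair[2], 1L, 2L, "Tanh", "Linear", "vector", w))
    expect_gt(n_parameters(bi), n_parameters(uni))
  }
  # analytic count for the 1-layer 2-unit toy GRU, vector head:
  # uni: W 1x6 + U 2x6 + b 6 + head 2x1 + 1 = 27; bi doubles the cell = 45 + wider head
  w <- window_spec(6L, 1L, 1L)
  uni <- build_model(model_spec("gru", 1L, 2L, "Tanh", "Linear", "vector", w))
  expect_identical(n_parameters(uni), 1L * 6L + 2L * 6L + 6L + 2L + 1L)
  bi <- build_model(model_spec("bi_gru", 1L, 2L, "Tanh", "Linear", "vector", w))
  expect_identical(n_parameters(bi), 2L * (6L + 12L + 6L) + 4L + 1L)
})

test_that("training runs exactly the configured epochs and records history", {
  set <- tiny_sets(n = 80, W = 8L)
  spec <- model_spec("gru", 1L, 3L, "Tanh", "Linear", "vector", window_spec(8L, 1L, 1L))
  fit <- train_predictor(spec, set, set, train_config(epochs = 5L, batch_size = 32L, seed = 2))
  expect_identical(nrow(fit$history), 5L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_identical(fit$status, "ok")
  expect_error(train_predictor(spec, make_supervised(1:3, window_spec(8L, 1L, 1L)),
                               config = train_config(epochs = 1L)), "empty")
})

test_that("any architecture memorizes a constant signal quickly", {
  const <- rep(0.5, 120)
  w <- window_spec(10L, 1L, 1L)
  set <- make_supervised(const, w)
  for (arch in c("gru", "bi_simple_rnn", "cnn_lstm")) {
    rc <- recommended_config(arch)
    spec <- model_spec(arch, 1L, 4L, rc$spec$hidden_activation,
                       rc$spec$output_activation, "vector", w)
    fit <- train_predictor(spec, set,
                           config = train_config("Adam", rc$config$learning_rate,
                                                 epochs = 50L, batch_size = 64L,
                                                 loss = "MSE", seed = 3))
    expect_lt(tail(fit$history$train_loss, 1), 1e-4)
    preds <- predict(fit, set)
    expect_true(all(abs(preds - 0.5) < 0.01))
  }
})

test_that("prediction is pure, order-preserving and weight-frozen", {
  set <- tiny_sets(n = 100, W = 8L)
  spec <- model_spec("gru", 2L, 3L, "Elu", "Linear", "encoder_decoder",
                     window_spec(8L, 1L, 1L))
  fit <- train_predictor(spec, set, config = train_config(epochs = 10L, seed = 9))
  w_before <- fit$params
  p1 <- predict(fit, set$inputs)
  p2 <- predict(fit, set$inputs)
  expect_identical(p1, p2)
  expect_identical(fit$params, w_before)   # frozen weights
  # batches preserve row order
  p_sub <- predict(fit, set$inputs[c(3, 1, 7), ])
  expect_equal(p_sub, p1[c(3, 1, 7), , drop = FALSE], tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 2, 5)), "expects W = 8")
})

test_that("same seed and data give identical training trajectories", {
  set <- tiny_sets(n = 90, W = 6L)
  spec <- model_spec("lstm", 1L, 3L, "Relu", "Linear", "vector", window_spec(6L, 1L, 1L))
  f1 <- train_predictor(spec, set, config = train_config(epochs = 8L, seed = 21))
  f2 <- train_predictor(spec, set, config = train_config(epochs = 8L, seed = 21))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("vector and encoder-decoder heads agree in output shape for every (W, O)", {
  for (geom in list(c(6L, 1L), c(8L, 3L), c(10L, 5L))) {
    W <- geom[1]; O <- geom[2]
    X <- matrix(rnorm(4 * W), 4, W)
    for (head in c("vector", "encoder_decoder")) {
      spec <- model_spec("gru", 1L, 3L, "Tanh", "Linear", head,
                         window_spec(W, O, 1L))
      m <- build_model(spec, seed = 1)
      fit <- train_predictor(m, make_supervised(sin(1:60) / 2 + 0.5, spec$window),
                             config = train_config(epochs = 1L, seed = 1))
      expect_identical(dim(predict(fit, X)), c(4L, O))
    }
  }
})

test_that("compiled whole-network path agrees with the layerwise reference path", {
  ns <- asNamespace("respredict")
  for (arch in c("gru", "bi_lstm", "cnn_lstm")) {
    spec <- model_spec(arch, 2L, 3L, "Elu", "Sigmoid", "encoder_decoder",
                       window_spec(9L, 2L, 1L))
    m <- build_model(spec, seed = 8)
    X <- ns$inputs_to_cube(matrix(with_fixed_seed(1, rnorm(5 * 9)), 5, 9))
    Y <- matrix(with_fixed_seed(2, rnorm(10)), 5, 2)
    fw <- ns$model_forward(m, m$params, X)
    gR <- ns$model_backward(m, m$params, fw, ns$loss_backward(fw$Y, Y, "MSE"))
    st <- ns$.net_step(X, Y, m$params, ns$.net_descriptor(m, "MSE"))
    expect_equal(st$Y, fw$Y, tolerance = 1e-12)
    for (nm in names(m$params))
      expect_equal(as.numeric(st$grads[[nm]]), as.numeric(gR[[nm]]),
                   tolerance = 1e-9)
  }
})

test_that("divergent training is reported as a failed run, not an error", {
  set <- tiny_sets(n = 80, W = 6L)
  spec <- model_spec("simple_rnn", 2L, 8L, "Relu", "Linear", "vector",
                     window_spec(6L, 1L, 1L))
  fit <- train_predictor(spec, set,
                         config = train_config("SGD", learning_rate = 1e4,
                                               epochs = 20L, seed = 1))
  expect_identical(fit$status, "diverged")
})

test_that("predictor bundles round-trip through save/load", {
  set <- tiny_sets(n = 80, W = 6L)
  spec <- model_spec("gru", 1L, 3L, "Tanh", "Linear", "vector", window_spec(6L, 1L, 1L))
  fit <- train_predictor(spec, set, config = train_config(epochs = 3L, seed = 4))
  stem <- tempfile()
  save_predictor(fit, stem, norm = normalizer(-2, 13))
  back <- load_predictor(stem)
  expect_identical(back$predictor$params, fit$params)
  expect_equal(back$norm$y_max, 13)
  expect_identical(predict(back$predictor, set$inputs), predict(fit, set$inputs))
  manifest <- jsonlite::read_json(paste0(stem, "_manifest.json"))
  expect_identical(manifest$architecture, "gru")
})
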