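#' The seven forecasting architectures
#'
#' @return Character vector of the seven architecture names.
#' @export
architectures <- function() {
  c("simple_rnn", "lstm", "gru", "bi_simple_rnn", "bi_lstm", "bi_gru", "cnn_lstm")
}

.arch_cell <- function(architecture) {
  switch(architecture,
    simple_rnn = , bi_simple_rnn = "rnn",
    lstm = , bi_lstm = , cnn_lstm = "lstm",
    gru = , bi_gru = "gru")
}
.arch_bidir <- function(architecture) architecture %in% c("bi_simple_rnn", "bi_lstm", "bi_gru")

#' Model specification
#'
#' Describes one predictor: architecture, depth and width, activations,
#' multistep head type and the sliding-window geometry it consumes.
#' `n_layers` counts recurrent layers; for `cnn_lstm` a fixed width-3,
#' `units_per_layer`-filter convolution plus width-2 max-pool feature stage
#' precedes them and is not counted.
#'
#' @param architecture One of [architectures()].
#' @param n_layers Number of recurrent layers (>= 1).
#' @param units_per_layer Hidden units per layer (>= 1).
#' @param hidden_activation Hidden-layer activation name (see
#'   [activation_names()]).
#' @param output_activation Output-layer activation name: Linear, Sigmoid,
#'   Swish or Softsign.
#' @param multistep `"encoder_decoder"` (the O outputs are generated
#'   recurrently by a decoder cell fed the repeated context vector) or
#'   `"vector"` (one dense projection emits all O outputs).
#' @param window A [window_spec()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture, n_layers, units_per_layer,
                       hidden_activation, output_activation,
                       multistep = c("encoder_decoder", "vector"),
                       window = window_spec(50L, 1L, 1L)) {
  if (!architecture %in% architectures())
    stopf("unknown architecture '%s' (use one of: %s)", architecture,
          paste(architectures(), collapse = ", "))
  multistep <- match.arg(multistep)
  if (!inherits(window, "window_spec")) stopf("`window` must be a window_spec")
  for (nm in c("n_layers", "units_per_layer")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stopf("`%s` must be an integer >= 1", nm)
  }
  act_id(hidden_activation, "hidden")   # validates
  act_id(output_activation, "output")   # rejects e.g. Softmax for regression
  if (architecture == "cnn_lstm" && window$input_len < 4L)
    stopf("cnn_lstm needs an input window of at least 4 samples (width-3 convolution + width-2 pooling)")
  structure(list(architecture = architecture, n_layers = as.integer(n_layers),
                 units_per_layer = as.integer(units_per_layer),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 multistep = multistep, window = window),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d layer(s) x %d units, hidden=%s, output=%s, %s head\n",
              x$architecture, x$n_layers, x$units_per_layer,
              x$hidden_activation, x$output_activation, x$multistep))
  print(x$window)
  invisible(x)
}

#' Training configuration
#'
#' @param optimizer One of [optimizer_names()].
#' @param learning_rate Positive step size.
#' @param epochs Number of full passes over the training pairs (>= 1); training
#'   always runs exactly this many epochs (no early stopping).
#' @param batch_size Minibatch size (>= 1).
#' @param loss One of [loss_names()].
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "Adam", learning_rate = 0.001,
                         epochs = 500L, batch_size = 200L, loss = "MSE",
                         seed = 1L) {
  if (!optimizer %in% optimizer_names())
    stopf("unknown optimizer '%s'", optimizer)
  if (!loss %in% loss_names()) stopf("unknown loss '%s'", loss)
  assert_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  for (nm in c("epochs", "batch_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stopf("`%s` must be an integer >= 1", nm)
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 loss = loss, seed = as.integer(seed)), class = "train_config")
}

# Recommended per-architecture configurations (tuned-selection table).
.recommended_table <- list(
  simple_rnn    = list(n_layers = 2L, units = 10L, optimizer = "Adam", lr = 0.001,
                       hidden = "Swish", output = "Linear", epochs = 500L,
                       latency = 1L, batch = 300L, loss = "MSE"),
  lstm          = list(n_layers = 2L, units = 10L, optimizer = "Adam", lr = 0.005,
                       hidden = "Relu", output = "Linear", epochs = 500L,
                       latency = 1L, batch = 250L, loss = "MSE"),
  gru           = list(n_layers = 3L, units = 10L, optimizer = "Adam", lr = 0.005,
                       hidden = "Elu", output = "Linear", epochs = 1000L,
                       latency = 1L, batch = 200L, loss = "MSE"),
  bi_simple_rnn = list(n_layers = 3L, units = 5L, optimizer = "Adam", lr = 0.001,
                       hidden = "Tanh", output = "Softsign", epochs = 500L,
                       latency = 1L, batch = 300L, loss = "MAE"),
  bi_lstm       = list(n_layers = 2L, units = 5L, optimizer = "Adam", lr = 0.005,
                       hidden = "Softsign", output = "Linear", epochs = 500L,
                       latency = 1L, batch = 200L, loss = "MAE"),
  bi_gru        = list(n_layers = 3L, units = 5L, optimizer = "Adam", lr = 0.003,
                       hidden = "Softsign", output = "Sigmoid", epochs = 1000L,
                       latency = 1L, batch = 200L, loss = "MAE"),
  cnn_lstm      = list(n_layers = 1L, units = 20L, optimizer = "Adam", lr = 0.003,
                       hidden = "Tanh", output = "Swish", epochs = 500L,
                       latency = 1L, batch = 200L, loss = "MAE")
)

#' Recommended (tuned) configuration for an architecture
#'
#' Returns the per-architecture configuration selected by the grouped
#' hyperparameter search: input window 50, output window 1, horizon 1 sample,
#' encoder-decoder multistep head, Adam optimizer throughout, with
#' per-architecture depth, width, activations, learning rate, epochs, batch
#' size and loss.
#'
#' @param architecture One of [architectures()].
#' @param seed Seed stored in the returned [train_config()].
#' @return List with elements `spec` ([model_spec()]) and
#'   `config` ([train_config()]).
#' @export
#' @examples
#' recommended_config("gru")$spec
recommended_config <- function(architecture, seed = 1L) {
  if (!architecture %in% architectures())
    stopf("unknown architecture '%s'", architecture)
  r <- .recommended_table[[architecture]]
  list(
    spec = model_spec(architecture, r$n_layers, r$units, r$hidden, r$output,
                      multistep = "encoder_decoder",
                      window = window_spec(50L, 1L, r$latency)),
    config = train_config(r$optimizer, r$lr, r$epochs, r$batch, r$loss, seed)
  )
}

.glorot <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

.cell_gates <- function(cell) switch(cell, rnn = 1L, gru = 3L, lstm = 4L)

.init_cell_params <- function(cell, in_dim, units) {
  m <- .cell_gates(cell)
  b <- numeric(m * units)
  if (cell == "lstm") b[units + seq_len(units)] <- 1  # forget-gate bias
  list(W = .glorot(in_dim, units, c(in_dim, m * units)),
       U = .glorot(units, units, c(units, m * units)),
       b = b)
}

#' Build an untrained predictor network from a specification
#'
#' Constructs the layer stack and initializes every weight (Glorot-uniform,
#' LSTM forget-gate biases at 1) under `seed`: identical `(spec, seed)` pairs
#' produce bitwise-identical initial parameters. Bidirectional variants hold
#' separate forward and reverse cells per layer; `cnn_lstm` prepends the fixed
#' convolution + max-pool stage. The encoder-decoder head adds one decoder
#' cell (same cell family, same width) plus a per-step scalar projection; the
#' vector head is a single dense projection to all O outputs.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `predictor_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "model_spec")) stopf("`spec` must be a model_spec")
  cell <- .arch_cell(spec$architecture)
  bidir <- .arch_bidir(spec$architecture)
  hid <- act_id(spec$hidden_activation, "hidden")
  out <- act_id(spec$output_activation, "output")
  H <- spec$units_per_layer
  layers <- list()
  params <- list()
  with_seed(seed, {
    in_dim <- 1L
    li <- 0L
    if (spec$architecture == "cnn_lstm") {
      li <- li + 1L
      nm <- sprintf("L%d", li)
      layers[[li]] <- list(name = nm, type = "conv", act = hid, bidir = FALSE)
      params[[paste0(nm, ".K")]] <- .glorot(in_dim * 3L, H * 3L, c(in_dim, H, 3L))
      params[[paste0(nm, ".cb")]] <- numeric(H)
      in_dim <- H
    }
    for (l in seq_len(spec$n_layers)) {
      li <- li + 1L
      nm <- sprintf("L%d", li)
      layers[[li]] <- list(name = nm, type = "cell", cell = cell, act = hid,
                           bidir = bidir)
      if (bidir) {
        for (dir in c("fwd", "bwd")) {
          p <- .init_cell_params(cell, in_dim, H)
          params[[paste0(nm, ".", dir, ".W")]] <- p$W
          params[[paste0(nm, ".", dir, ".U")]] <- p$U
          params[[paste0(nm, ".", dir, ".b")]] <- p$b
        }
        in_dim <- 2L * H
      } else {
        p <- .init_cell_params(cell, in_dim, H)
        params[[paste0(nm, ".W")]] <- p$W
        params[[paste0(nm, ".U")]] <- p$U
        params[[paste0(nm, ".b")]] <- p$b
        in_dim <- H
      }
    }
    O <- spec$window$output_len
    if (spec$multistep == "vector") {
      head <- list(type = "vector", out_act = out)
      params[["head.W"]] <- .glorot(in_dim, O, c(in_dim, O))
      params[["head.b"]] <- numeric(O)
    } else {
      head <- list(type = "encdec", cell = cell, out_act = out, dec_act = hid)
      p <- .init_cell_params(cell, in_dim, H)
      params[["dec.W"]] <- p$W
      params[["dec.U"]] <- p$U
      params[["dec.b"]] <- p$b
      params[["head.W"]] <- .glorot(H, 1L, c(H, 1L))
      params[["head.b"]] <- 0
    }
    structure(list(spec = spec, layers = layers, head = head, params = params,
                   seed = as.integer(seed)),
              class = "predictor_model")
  })
}

#' Number of trainable parameters
#' @param model A `predictor_model` or `trained_predictor`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("<predictor_model> %s (untrained), %d parameters\n",
              x$spec$architecture, n_parameters(x)))
  invisible(x)
}

# Compact integer descriptor consumed by the compiled whole-network kernels.
.net_descriptor <- function(model, loss = "MSE") {
  ltype <- vapply(model$layers, function(l)
    if (l$type == "conv") 2L else if (isTRUE(l$bidir)) 1L else 0L, integer(1))
  cellid <- vapply(model$layers, function(l)
    if (l$type == "conv") 0L else switch(l$cell, rnn = 0L, gru = 1L, lstm = 2L),
    integer(1))
  list(ltype = ltype, cell = cellid,
       act = model$layers[[length(model$layers)]]$act,
       htype = if (model$head$type == "vector") 0L else 1L,
       out_act = model$head$out_act,
       loss = c(MSE = 0L, MAE = 1L, Huber = 2L, LogCosh = 3L)[[loss]],
       O = model$spec$window$output_len)
}

.check_set <- function(set, spec, what) {
  if (!inherits(set, "supervised_set")) stopf("`%s` must be a supervised_set", what)
  if (set$spec$input_len != spec$window$input_len ||
      set$spec$output_len != spec$window$output_len)
    stopf("`%s` window (W=%d, O=%d) does not match the model spec (W=%d, O=%d)",
          what, set$spec$input_len, set$spec$output_len,
          spec$window$input_len, spec$window$output_len)
  invisible(set)
}

#' Train a predictor
#'
#' Minibatch gradient descent through time for exactly `config$epochs` epochs
#' (no early stopping), with per-epoch training and validation losses recorded.
#' Weights are frozen afterwards: prediction never updates them. A run whose
#' loss becomes non-finite is returned with `status = "diverged"` instead of
#' raising, so hyperparameter sweeps can score it as a failed trial.
#'
#' @param model A `predictor_model` from [build_model()], or a [model_spec()]
#'   (then the network is built under `config$seed`).
#' @param train_set,val_set [make_supervised()] sets on the normalized scale;
#'   `val_set` may be `NULL` or empty (validation losses are then `NA`).
#' @param config A [train_config()].
#' @param verbose Print a progress line every `verbose` epochs (0 = silent).
#' @return An object of class `trained_predictor` with fields `spec`,
#'   `config`, `params`, `history` (data.frame: epoch, train_loss, val_loss)
#'   and `status` (`"ok"` or `"diverged"`).
#' @export
train_predictor <- function(model, train_set, val_set = NULL, config = train_config(),
                            verbose = 0) {
  if (inherits(model, "model_spec")) model <- build_model(model, seed = config$seed)
  if (!inherits(model, "predictor_model")) stopf("`model` must be a predictor_model")
  if (!inherits(config, "train_config")) stopf("`config` must be a train_config")
  .check_set(train_set, model$spec, "train_set")
  n <- n_pairs(train_set)
  if (n == 0L) stopf("training set is empty")
  has_val <- !is.null(val_set) && n_pairs(val_set) > 0L
  if (has_val) .check_set(val_set, model$spec, "val_set")

  Xall <- inputs_to_cube(train_set$inputs)
  Yall <- train_set$targets
  if (has_val) {
    Xval <- inputs_to_cube(val_set$inputs)
    Yval <- val_set$targets
  }
  params <- model$params
  nspec <- .net_descriptor(model, config$loss)
  opt <- optimizer_init(config$optimizer, config$learning_rate)
  bs <- min(config$batch_size, n)
  hist_train <- hist_val <- rep(NA_real_, config$epochs)
  status <- "ok"

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      ep_loss <- 0; ep_n <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, n)]
        sr <- .net_step(Xall[idx, , , drop = FALSE], Yall[idx, , drop = FALSE],
                        params, nspec)
        if (!is.finite(sr$loss)) { status <- "diverged"; break }
        st <- optimizer_step(opt, params, sr$grads)
        opt <- st$opt; params <- st$params
        ep_loss <- ep_loss + sr$loss * length(idx); ep_n <- ep_n + length(idx)
      }
      if (status == "diverged") {
        hist_train[ep] <- NaN
        break
      }
      hist_train[ep] <- ep_loss / ep_n
      if (has_val) {
        pv <- .predict_params(model, params, Xval, nspec = nspec)
        hist_val[ep] <- loss_forward(pv, Yval, config$loss)
        if (!is.finite(hist_val[ep])) { status <- "diverged"; break }
      }
      if (verbose > 0 && (ep %% verbose == 0 || ep == config$epochs))
        message(sprintf("epoch %d/%d: train %s = %.6f%s", ep, config$epochs,
                        config$loss, hist_train[ep],
                        if (has_val) sprintf(", val = %.6f", hist_val[ep]) else ""))
    }
  })
  structure(list(spec = model$spec, config = config, params = params,
                 layers = model$layers, head = model$head,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 status = status),
            class = "trained_predictor")
}

# forward-only prediction in memory-bounded chunks
.predict_params <- function(model, params, Xcube, chunk = 4096L, nspec = NULL) {
  if (is.null(nspec)) nspec <- .net_descriptor(model)
  n <- dim(Xcube)[1]
  O <- model$spec$window$output_len
  out <- matrix(0, n, O)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx, ] <- .net_predict(Xcube[idx, , , drop = FALSE], params, nspec)
  }
  out
}

#' @export
print.trained_predictor <- function(x, ...) {
  fl <- x$history$train_loss[max(which(is.finite(x$history$train_loss)), 1)]
  cat(sprintf("<trained_predictor> %s, %d parameters, %d epochs [%s], final train %s = %.3g\n",
              x$spec$architecture, n_parameters(x), nrow(x$history), x$status,
              x$config$loss, fl))
  invisible(x)
}

#' Predict future samples from input windows
#'
#' A pure function of the frozen weights and the inputs: repeated calls on the
#' same inputs return identical outputs and never mutate the predictor.
#'
#' @param object A `trained_predictor`.
#' @param inputs An n x W numeric matrix, a single length-W vector, or a
#'   supervised_set (its `inputs` are used).
#' @param ... Unused.
#' @return n x O matrix of predictions in normalized units, rows in input order.
#' @export
predict.trained_predictor <- function(object, inputs, ...) {
  if (inherits(inputs, "supervised_set")) inputs <- inputs$inputs
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1L)
  W <- object$spec$window$input_len
  if (ncol(inputs) != W)
    stopf("inputs have %d columns but the model expects W = %d", ncol(inputs), W)
  .predict_params(object, object$params, inputs_to_cube(inputs))
}
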