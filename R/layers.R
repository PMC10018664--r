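# Layer orchestration over the compiled cell kernels. Sequences are 3-d
# arrays (batch, features, time); univariate breathing windows enter as
# (batch, 1, W) cubes. Bidirectional layers run the cell over the window in
# both directions and concatenate features; their per-timestep output aligns
# the reverse pass so position t carries the state after reading T..t, and
# the head receives both directions' full-pass final states.

.cell_forward <- function(type, X, W, U, b, act) {
  B <- dim(X)[1]; H <- ncol(W) / switch(type, rnn = 1L, gru = 3L, lstm = 4L)
  h0 <- matrix(0, B, H)
  switch(type,
    rnn = .rnn_forward(X, W, U, b, h0, act),
    gru = .gru_forward(X, W, U, b, h0, act),
    lstm = .lstm_forward(X, W, U, b, h0, matrix(0, B, H), act)
  )
}

.cell_backward <- function(type, X, W, U, cache, dH, act) {
  B <- dim(X)[1]; H <- dim(cache$H)[2]
  h0 <- matrix(0, B, H)
  switch(type,
    rnn = .rnn_backward(X, W, U, h0, cache$H, cache$P, dH, act),
    gru = .gru_backward(X, W, U, h0, cache$H, cache$Z, cache$R, cache$C,
                        cache$Pc, dH, act),
    lstm = .lstm_backward(X, W, U, h0, matrix(0, B, H), cache$H, cache$I,
                          cache$F, cache$G, cache$O, cache$Cs, cache$Pg,
                          cache$Hc, dH, act)
  )
}

.rev_time <- function(X) {
  T <- dim(X)[3]
  X[, , T:1, drop = FALSE]
}

layer_forward <- function(layer, params, X) {
  pfx <- layer$name
  if (layer$type == "conv") {
    res <- .conv1d_forward(X, params[[paste0(pfx, ".K")]],
                           params[[paste0(pfx, ".cb")]], layer$act)
    return(list(out = res$Out, cache = res, head_vec = NULL))
  }
  if (layer$bidir) {
    T <- dim(X)[3]
    fwd <- .cell_forward(layer$cell, X, params[[paste0(pfx, ".fwd.W")]],
                         params[[paste0(pfx, ".fwd.U")]],
                         params[[paste0(pfx, ".fwd.b")]], layer$act)
    bwd <- .cell_forward(layer$cell, .rev_time(X), params[[paste0(pfx, ".bwd.W")]],
                         params[[paste0(pfx, ".bwd.U")]],
                         params[[paste0(pfx, ".bwd.b")]], layer$act)
    H <- dim(fwd$H)[2]; B <- dim(X)[1]
    out <- array(0, c(B, 2L * H, T))
    out[, seq_len(H), ] <- fwd$H
    out[, H + seq_len(H), ] <- .rev_time(bwd$H)
    head_vec <- cbind(fwd$H[, , T, drop = TRUE], bwd$H[, , T, drop = TRUE])
    if (B == 1L) head_vec <- matrix(head_vec, 1L)
    list(out = out, cache = list(fwd = fwd, bwd = bwd), head_vec = head_vec)
  } else {
    res <- .cell_forward(layer$cell, X, params[[paste0(pfx, ".W")]],
                         params[[paste0(pfx, ".U")]],
                         params[[paste0(pfx, ".b")]], layer$act)
    T <- dim(res$H)[3]
    hv <- res$H[, , T, drop = TRUE]
    if (dim(X)[1] == 1L) hv <- matrix(hv, 1L)
    list(out = res$H, cache = res, head_vec = hv)
  }
}

# dOut: gradient wrt the layer's aligned output sequence; d_head: gradient wrt
# the head vector (only non-NULL for the final recurrent layer).
layer_backward <- function(layer, params, X, cache, dOut, d_head = NULL) {
  pfx <- layer$name
  grads <- list()
  if (layer$type == "conv") {
    res <- .conv1d_backward(X, params[[paste0(pfx, ".K")]], cache$P, cache$Y,
                            cache$Amax, dOut, layer$act)
    grads[[paste0(pfx, ".K")]] <- res$dK
    grads[[paste0(pfx, ".cb")]] <- as.numeric(res$db)
    return(list(dX = res$dX, grads = grads))
  }
  T <- dim(X)[3]
  if (layer$bidir) {
    H <- dim(cache$fwd$H)[2]
    dF <- dOut[, seq_len(H), , drop = FALSE]
    dG <- .rev_time(dOut[, H + seq_len(H), , drop = FALSE])
    if (!is.null(d_head)) {
      dF[, , T] <- dF[, , T] + d_head[, seq_len(H)]
      dG[, , T] <- dG[, , T] + d_head[, H + seq_len(H)]
    }
    rf <- .cell_backward(layer$cell, X, params[[paste0(pfx, ".fwd.W")]],
                         params[[paste0(pfx, ".fwd.U")]], cache$fwd, dF, layer$act)
    rb <- .cell_backward(layer$cell, .rev_time(X), params[[paste0(pfx, ".bwd.W")]],
                         params[[paste0(pfx, ".bwd.U")]], cache$bwd, dG, layer$act)
    grads[[paste0(pfx, ".fwd.W")]] <- rf$dW
    grads[[paste0(pfx, ".fwd.U")]] <- rf$dU
    grads[[paste0(pfx, ".fwd.b")]] <- as.numeric(rf$db)
    grads[[paste0(pfx, ".bwd.W")]] <- rb$dW
    grads[[paste0(pfx, ".bwd.U")]] <- rb$dU
    grads[[paste0(pfx, ".bwd.b")]] <- as.numeric(rb$db)
    list(dX = rf$dX + .rev_time(rb$dX), grads = grads)
  } else {
    if (!is.null(d_head)) dOut[, , T] <- dOut[, , T] + d_head
    res <- .cell_backward(layer$cell, X, params[[paste0(pfx, ".W")]],
                          params[[paste0(pfx, ".U")]], cache, dOut, layer$act)
    grads[[paste0(pfx, ".W")]] <- res$dW
    grads[[paste0(pfx, ".U")]] <- res$dU
    grads[[paste0(pfx, ".b")]] <- as.numeric(res$db)
    list(dX = res$dX, grads = grads)
  }
}

# Full-network forward pass. X: (B, 1, W) array. Returns predictions (B x O)
# plus every cache needed for the backward pass.
model_forward <- function(model, params, X) {
  caches <- vector("list", length(model$layers))
  A <- X
  head_vec <- NULL
  for (l in seq_along(model$layers)) {
    res <- layer_forward(model$layers[[l]], params, A)
    caches[[l]] <- list(X = A, cache = res$cache)
    head_vec <- res$head_vec
    A <- res$out
  }
  O <- model$spec$window$output_len
  B <- dim(X)[1]
  if (model$head$type == "vector") {
    P <- head_vec %*% params[["head.W"]] +
      matrix(params[["head.b"]], B, O, byrow = TRUE)
    Y <- act_forward(P, model$head$out_act)
    list(Y = Y, P = P, caches = caches, head_vec = head_vec)
  } else {
    D <- ncol(head_vec)
    Xdec <- array(head_vec, c(B, D, O))   # context repeated O times
    dec <- .cell_forward(model$head$cell, Xdec, params[["dec.W"]],
                         params[["dec.U"]], params[["dec.b"]], model$head$dec_act)
    Hq <- dec$H
    P <- matrix(0, B, O)
    for (o in seq_len(O))
      P[, o] <- Hq[, , o, drop = TRUE] %*% params[["head.W"]] + params[["head.b"]]
    Y <- act_forward(P, model$head$out_act)
    list(Y = Y, P = P, caches = caches, head_vec = head_vec,
         dec = dec, Xdec = Xdec)
  }
}

model_backward <- function(model, params, fw, dY) {
  grads <- list()
  dP <- act_backward(dY, fw$P, fw$Y, model$head$out_act)
  B <- nrow(dP); O <- ncol(dP)
  if (model$head$type == "vector") {
    grads[["head.W"]] <- t(fw$head_vec) %*% dP
    grads[["head.b"]] <- colSums(dP)
    d_head <- dP %*% t(params[["head.W"]])
  } else {
    Hq <- fw$dec$H
    Hdim <- dim(Hq)[2]
    dW <- matrix(0, Hdim, 1)
    dHdec <- array(0, c(B, Hdim, O))
    w <- params[["head.W"]]
    for (o in seq_len(O)) {
      ho <- matrix(Hq[, , o], B, Hdim)
      dW <- dW + t(ho) %*% dP[, o, drop = FALSE]
      dHdec[, , o] <- dP[, o] %*% t(w)
    }
    grads[["head.W"]] <- dW
    grads[["head.b"]] <- sum(dP)
    res <- .cell_backward(model$head$cell, fw$Xdec, params[["dec.W"]],
                          params[["dec.U"]], fw$dec, dHdec, model$head$dec_act)
    grads[["dec.W"]] <- res$dW
    grads[["dec.U"]] <- res$dU
    grads[["dec.b"]] <- as.numeric(res$db)
    d_head <- apply(res$dX, c(1, 2), sum)   # context fed at every decoder step
    if (B == 1L) d_head <- matrix(d_head, 1L)
  }
  nl <- length(model$layers)
  # the final recurrent layer receives gradient only through the head vector
  last <- model$layers[[nl]]
  last_cache <- fw$caches[[nl]]$cache
  dOut <- if (last$bidir) {
    d <- dim(last_cache$fwd$H)
    array(0, c(d[1], 2L * d[2], d[3]))
  } else {
    array(0, dim(last_cache$H))
  }
  for (l in rev(seq_len(nl))) {
    layer <- model$layers[[l]]
    st <- fw$caches[[l]]
    res <- layer_backward(layer, params, st$X, st$cache, dOut,
                          d_head = if (l == nl) d_head else NULL)
    for (nm in names(res$grads)) grads[[nm]] <- res$grads[[nm]]
    dOut <- res$dX
  }
  grads
}

# supervised-set inputs (n x W) as a (n, 1, W) cube
inputs_to_cube <- function(inputs) {
  n <- nrow(inputs); W <- ncol(inputs)
  arr <- array(0, c(n, 1L, W))
  arr[, 1L, ] <- inputs
  arr
}
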