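# First-order optimizers. Parameters and gradients are flat named lists of
# numeric arrays; updates are elementwise, so every optimizer works on any
# architecture. Hyperparameters follow the common Keras-era defaults.

.optimizer_names <- c("SGD", "Adam", "Adamax", "Nesterov Adam", "Adagrad",
                      "Adadelta", "RMSprop", "FTRL")

#' Supported optimizers
#' @return Character vector of optimizer names.
#' @export
optimizer_names <- function() .optimizer_names

optimizer_init <- function(name, lr) {
  if (!name %in% .optimizer_names)
    stopf("unknown optimizer '%s' (use one of: %s)", name,
          paste(.optimizer_names, collapse = ", "))
  assert_scalar_num(lr, "learning_rate", positive = TRUE)
  list(name = name, lr = lr, t = 0L, state = NULL,
       beta1 = 0.9, beta2 = 0.999, rho = 0.9, rho_delta = 0.95,
       eps = 1e-7, ftrl_beta = 1)
}

.zeros_like <- function(params) lapply(params, function(p) p * 0)

optimizer_step <- function(opt, params, grads) {
  if (is.null(opt$state)) {
    opt$state <- switch(opt$name,
      SGD = list(),
      Adam = , Adamax = , `Nesterov Adam` =
        list(m = .zeros_like(params), v = .zeros_like(params)),
      Adagrad = list(a = .zeros_like(params)),
      Adadelta = list(ag = .zeros_like(params), ad = .zeros_like(params)),
      RMSprop = list(a = .zeros_like(params)),
      FTRL = list(z = .zeros_like(params), n = .zeros_like(params))
    )
  }
  opt$t <- opt$t + 1L
  t <- opt$t; lr <- opt$lr; eps <- opt$eps
  b1 <- opt$beta1; b2 <- opt$beta2
  for (k in names(params)) {
    g <- grads[[k]]
    p <- params[[k]]
    if (is.null(g) || length(g) != length(p))
      stopf("gradient for '%s' is missing or misshaped", k)
    attributes(g) <- attributes(p)   # conform rowvec/scalar returns to p's shape
    switch(opt$name,
      SGD = {
        params[[k]] <- p - lr * g
      },
      Adam = {
        opt$state$m[[k]] <- b1 * opt$state$m[[k]] + (1 - b1) * g
        opt$state$v[[k]] <- b2 * opt$state$v[[k]] + (1 - b2) * g^2
        mh <- opt$state$m[[k]] / (1 - b1^t)
        vh <- opt$state$v[[k]] / (1 - b2^t)
        params[[k]] <- p - lr * mh / (sqrt(vh) + eps)
      },
      Adamax = {
        opt$state$m[[k]] <- b1 * opt$state$m[[k]] + (1 - b1) * g
        opt$state$v[[k]] <- pmax(b2 * opt$state$v[[k]], abs(g))
        params[[k]] <- p - (lr / (1 - b1^t)) * opt$state$m[[k]] /
          (opt$state$v[[k]] + eps)
      },
      `Nesterov Adam` = {
        opt$state$m[[k]] <- b1 * opt$state$m[[k]] + (1 - b1) * g
        opt$state$v[[k]] <- b2 * opt$state$v[[k]] + (1 - b2) * g^2
        mh <- opt$state$m[[k]] / (1 - b1^(t + 1))
        vh <- opt$state$v[[k]] / (1 - b2^t)
        params[[k]] <- p - lr * (b1 * mh + (1 - b1) * g / (1 - b1^t)) /
          (sqrt(vh) + eps)
      },
      Adagrad = {
        opt$state$a[[k]] <- opt$state$a[[k]] + g^2
        params[[k]] <- p - lr * g / (sqrt(opt$state$a[[k]]) + eps)
      },
      Adadelta = {
        rho <- opt$rho_delta
        opt$state$ag[[k]] <- rho * opt$state$ag[[k]] + (1 - rho) * g^2
        step <- sqrt(opt$state$ad[[k]] + eps) / sqrt(opt$state$ag[[k]] + eps) * g
        opt$state$ad[[k]] <- rho * opt$state$ad[[k]] + (1 - rho) * step^2
        params[[k]] <- p - lr * step
      },
      RMSprop = {
        opt$state$a[[k]] <- opt$rho * opt$state$a[[k]] + (1 - opt$rho) * g^2
        params[[k]] <- p - lr * g / (sqrt(opt$state$a[[k]]) + eps)
      },
      FTRL = {
        n_old <- opt$state$n[[k]]
        n_new <- n_old + g^2
        sigma <- (sqrt(n_new) - sqrt(n_old)) / lr
        opt$state$z[[k]] <- opt$state$z[[k]] + g - sigma * p
        opt$state$n[[k]] <- n_new
        params[[k]] <- -opt$state$z[[k]] * lr / (opt$ftrl_beta + sqrt(n_new))
      }
    )
    # elementwise arithmetic can promote scalars/vectors to 1-d arrays;
    # restore the parameter's original shape so downstream matrix ops conform
    attributes(params[[k]]) <- attributes(p)
  }
  list(opt = opt, params = params)
}
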