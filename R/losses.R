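# Training losses. Each returns the scalar loss and its gradient wrt the
# prediction matrix (n x O), averaged over all elements.

.loss_names <- c("MAE", "MSE", "Huber", "LogCosh")

#' Supported training loss functions
#' @return Character vector of loss names.
#' @export
loss_names <- function() .loss_names

loss_forward <- function(pred, target, loss) {
  d <- pred - target
  n <- length(d)
  switch(loss,
    MSE = mean(d^2),
    MAE = mean(abs(d)),
    Huber = {   # delta = 1
      a <- abs(d)
      mean(ifelse(a <= 1, 0.5 * d^2, a - 0.5))
    },
    LogCosh = {
      # log(cosh(d)) computed stably as |d| + log1p(exp(-2|d|)) - log 2
      a <- abs(d)
      mean(a + log1p(exp(-2 * a)) - log(2))
    },
    stopf("unknown loss '%s' (use one of: %s)", loss, paste(.loss_names, collapse = ", "))
  )
}

loss_backward <- function(pred, target, loss) {
  d <- pred - target
  n <- length(d)
  g <- switch(loss,
    MSE = 2 * d,
    MAE = sign(d),
    Huber = ifelse(abs(d) <= 1, d, sign(d)),
    LogCosh = tanh(d),
    stopf("unknown loss '%s'", loss)
  )
  g / n
}
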