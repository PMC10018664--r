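# Activation registry. Ids must stay in sync with src/cells.cpp.

.hidden_activations <- c(
  "Swish" = 10L, "Sigmoid" = 1L, "Relu" = 2L, "Selu" = 3L, "Elu" = 4L,
  "Softsign" = 5L, "Tanh" = 6L, "Softmax" = 7L, "Softplus" = 8L,
  "Hard Sigmoid" = 9L, "Linear" = 0L
)
.output_activations <- c(
  "Linear" = 0L, "Sigmoid" = 1L, "Swish" = 10L, "Softsign" = 5L
)

#' Supported activation functions
#'
#' @return Named list with the hidden-layer and output-layer activation names.
#' @export
activation_names <- function() {
  list(hidden = names(.hidden_activations), output = names(.output_activations))
}

act_id <- function(name, where = c("hidden", "output")) {
  where <- match.arg(where)
  tbl <- if (where == "hidden") .hidden_activations else .output_activations
  if (!name %in% names(tbl))
    stopf("'%s' is not a supported %s-layer activation (use one of: %s)",
          name, where, paste(names(tbl), collapse = ", "))
  tbl[[name]]
}

# R-side wrappers over the shared C++ definitions (used by the dense heads)
act_forward <- function(x, id) .act_apply(as.matrix(x), id)
act_backward <- function(dY, P, Y, id) .act_dpre(as.matrix(dY), as.matrix(P), as.matrix(Y), id)
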