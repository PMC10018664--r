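#' Chronological split specification
#'
#' Fractions of a signal assigned, in time order, to training, validation and
#' testing. The study partition is 35% / 5% / 60%.
#'
#' @param train_frac,val_frac,test_frac Non-negative fractions summing to 1
#'   (tolerance 1e-9).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.35, val_frac = 0.05, test_frac = 0.60) {
  for (nm in c("train_frac", "val_frac", "test_frac"))
    assert_scalar_num(get(nm), nm, nonneg = TRUE)
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stopf("split fractions must sum to 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac), class = "split_spec")
}

#' Split a signal chronologically into train/validation/test segments
#'
#' Segments are contiguous, non-overlapping and cover the whole signal, with
#' training earliest — the only causally valid layout for forecasting. Segment
#' lengths are `floor(train_frac * L)` and `floor(val_frac * L)`, with the
#' remainder going to test; a validation segment that rounds to zero on tiny
#' inputs is returned empty with a warning.
#'
#' @param signal A [breathing_signal()] or numeric vector (length >= 3).
#' @param spec A [split_spec()].
#' @return List with numeric elements `train`, `val`, `test`.
#' @export
#' @examples
#' lengths(split_signal(sin(1:1000), split_spec()))  # 350, 50, 600
split_signal <- function(signal, spec = split_spec()) {
  if (!inherits(spec, "split_spec")) stopf("`spec` must be a split_spec")
  x <- if (inherits(signal, "breathing_signal")) signal$samples else as.numeric(signal)
  L <- length(x)
  if (L < 3L) stopf("signal must have at least 3 samples to split")
  n_train <- floor(spec$train_frac * L)
  n_val <- floor(spec$val_frac * L)
  n_test <- L - n_train - n_val
  if (n_val == 0L && spec$val_frac > 0)
    warning("validation segment is empty: signal too short for val_frac", call. = FALSE)
  list(train = x[seq_len(n_train)],
       val = x[n_train + seq_len(n_val)],
       test = x[(n_train + n_val) + seq_len(n_test)])
}

#' Sliding-window specification
#'
#' @param input_len Input-sliding window length W in samples (>= 1): how many
#'   recent samples the predictor sees.
#' @param output_len Output-sliding window length O in samples (>= 1): how many
#'   future samples are predicted per step.
#' @param horizon Lookahead h in samples (>= 1) between the end of the input
#'   window and the first predicted sample; models the system latency.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(input_len, output_len = 1L, horizon = 1L) {
  for (nm in c("input_len", "output_len", "horizon")) {
    v <- get(nm)
    assert_scalar_num(v, nm)
    if (v < 1 || v != round(v)) stopf("`%s` must be an integer >= 1", nm)
  }
  structure(list(input_len = as.integer(input_len),
                 output_len = as.integer(output_len),
                 horizon = as.integer(horizon)), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> W=%d input, O=%d output, horizon h=%d samples\n",
              x$input_len, x$output_len, x$horizon))
  invisible(x)
}

#' Convert a hardware latency in milliseconds to a sample horizon
#'
#' Rounds `latency_ms * fs / 1000` to the nearest integer with a floor of 1:
#' the predictor always looks at least one step ahead. At the 26 Hz recording
#' rate the 115 ms robotic-response latency maps to 3 samples.
#'
#' @param latency_ms Latency in milliseconds (>= 0).
#' @param fs Sampling rate in Hz (> 0).
#' @return Integer horizon in samples.
#' @export
latency_to_samples <- function(latency_ms, fs = 26) {
  assert_scalar_num(latency_ms, "latency_ms", nonneg = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  max(1L, as.integer(round(latency_ms * fs / 1000)))
}

#' Build a latency-shifted supervised dataset from a sample sequence
#'
#' Pair i (0-based) has input `samples[i .. i+W-1]` and target
#' `samples[i+W+h-1 .. i+W+h+O-2]`; with h = 1 the target immediately follows
#' the input. The pair count is `L - W - h - O + 2`. A sequence shorter than
#' `W + h + O - 1` yields an empty set with status `"insufficient_length"`
#' rather than an error, so cohort runs can skip it explicitly.
#'
#' @param samples Numeric vector (normalized or mm).
#' @param spec A [window_spec()].
#' @param source_id Label recording which signal/segment the pairs came from.
#' @return An object of class `supervised_set` with matrix fields `inputs`
#'   (n x W) and `targets` (n x O), the `spec`, `source_id`, and a `status`
#'   of `"ok"` or `"insufficient_length"`.
#' @export
make_supervised <- function(samples, spec, source_id = "segment") {
  if (!inherits(spec, "window_spec")) stopf("`spec` must be a window_spec")
  x <- if (inherits(samples, "breathing_signal")) samples$samples else as.numeric(samples)
  W <- spec$input_len; O <- spec$output_len; h <- spec$horizon
  L <- length(x)
  n <- L - W - h - O + 2L
  if (n < 1L) {
    return(structure(list(
      inputs = matrix(numeric(0), 0L, W), targets = matrix(numeric(0), 0L, O),
      spec = spec, source_id = source_id, status = "insufficient_length"
    ), class = "supervised_set"))
  }
  idx <- seq_len(n)
  inputs <- matrix(0, n, W)
  for (j in seq_len(W)) inputs[, j] <- x[idx + (j - 1L)]
  targets <- matrix(0, n, O)
  for (j in seq_len(O)) targets[, j] <- x[idx + W + h - 2L + j]
  structure(list(inputs = inputs, targets = targets, spec = spec,
                 source_id = source_id, status = "ok"),
            class = "supervised_set")
}

#' @export
print.supervised_set <- function(x, ...) {
  cat(sprintf("<supervised_set> '%s': %d pairs (W=%d -> O=%d, h=%d) [%s]\n",
              x$source_id, nrow(x$inputs), x$spec$input_len,
              x$spec$output_len, x$spec$horizon, x$status))
  invisible(x)
}

#' Number of supervised pairs in a set
#' @param set A supervised_set.
#' @return Integer pair count.
#' @export
n_pairs <- function(set) {
  if (!inherits(set, "supervised_set")) stopf("`set` must be a supervised_set")
  nrow(set$inputs)
}

#' Export a supervised set to a two-file delimited-text layout
#'
#' Writes `<stem>_inputs.csv` and `<stem>_targets.csv` for inspection; not a
#' performance path.
#'
#' @param set A supervised_set.
#' @param stem Path stem for the two files.
#' @return Character vector of the two written paths, invisibly.
#' @export
export_supervised <- function(set, stem) {
  if (!inherits(set, "supervised_set")) stopf("`set` must be a supervised_set")
  paths <- paste0(stem, c("_inputs.csv", "_targets.csv"))
  utils::write.csv(as.data.frame(set$inputs), paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(set$targets), paths[2], row.names = FALSE)
  invisible(paths)
}
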