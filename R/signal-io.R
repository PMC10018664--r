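#' Write a breathing signal to a text file
#'
#' Plain-CSV dialect: comment lines starting with `#`, a header comment
#' `# fs_hz=<rate>`, then `time_s,amp_mm` columns. Amplitudes are serialized
#' with enough significant digits that a write/read round trip reproduces the
#' samples to better than 1e-5 mm.
#'
#' @param signal A [breathing_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  if (!inherits(signal, "breathing_signal")) stopf("`signal` must be a breathing_signal")
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  t <- (seq_along(signal$samples) - 1L) / signal$sampling_rate_hz
  writeLines(c(
    sprintf("# fs_hz=%.10g", signal$sampling_rate_hz),
    sprintf("# signal_id=%s", signal$signal_id),
    if (!is.null(signal$pattern)) sprintf("# pattern=%s", signal$pattern),
    "time_s,amp_mm",
    sprintf("%.9g,%.9g", t, signal$samples)
  ), con)
  invisible(path)
}

#' Read a breathing signal from a text file
#'
#' Accepts the dialect written by [write_signal()]: `#` comment lines (an
#' optional `# fs_hz=` header fixes the sampling rate), a `time_s,amp_mm`
#' column header, and one comma-separated sample per line. Without an `fs_hz`
#' header the rate is inferred as the reciprocal of the median timestamp
#' spacing. Malformed rows and non-monotone timestamps are rejected with
#' row-level diagnostics.
#'
#' @param path Input file path.
#' @return A [breathing_signal()].
#' @export
#' @examples
#' path <- system.file("extdata", "example_slow_deep_synthetic.csv",
#'                     package = "respredict")
#' read_signal(path)
read_signal <- function(path) {
  if (!file.exists(path)) stopf("signal file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  fs <- NA_real_; signal_id <- NULL; pattern <- NULL
  comments <- grepl("^\\s*#", lines)
  for (cm in lines[comments]) {
    m <- regmatches(cm, regexec("#\\s*(\\w+)\\s*=\\s*(\\S+)", cm))[[1]]
    if (length(m) == 3L) {
      if (m[2] == "fs_hz") fs <- suppressWarnings(as.numeric(m[3]))
      if (m[2] == "signal_id") signal_id <- m[3]
      if (m[2] == "pattern") pattern <- m[3]
    }
  }
  body_idx <- which(!comments & nzchar(trimws(lines)))
  body <- lines[body_idx]
  if (length(body) && grepl("^\\s*time_s\\s*,", body[1])) {
    body_idx <- body_idx[-1]; body <- body[-1]
  }
  if (length(body) < 2L) stopf("'%s': need at least 2 samples, found %d", path, length(body))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stopf("'%s': malformed row(s) at line(s) %s (expected 'time_s,amp_mm')",
          path, paste(utils::head(body_idx[bad], 5L), collapse = ", "))
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(t) | !is.finite(y))
  if (length(bad))
    stopf("'%s': non-numeric value(s) at line(s) %s", path,
          paste(utils::head(body_idx[bad], 5L), collapse = ", "))
  dt <- diff(t)
  if (any(dt <= 0))
    stopf("'%s': non-monotone timestamps at line(s) %s", path,
          paste(utils::head(body_idx[which(dt <= 0) + 1L], 5L), collapse = ", "))
  if (!is.finite(fs)) fs <- 1 / stats::median(dt)
  breathing_signal(y, fs, signal_id = signal_id %||% basename(path),
                   pattern = pattern)
}

#' Min-max normalizer
#'
#' Affine map sending the fitted minimum to 0 and maximum to 1, the
#' preprocessing applied to breathing amplitudes before network training.
#' Fit it on the training segment only and reuse it for validation/test to
#' avoid leakage.
#'
#' @param y_min,y_max Range endpoints in mm, `y_max > y_min` strictly.
#' @return An object of class `normalizer`.
#' @export
normalizer <- function(y_min, y_max) {
  assert_scalar_num(y_min, "y_min"); assert_scalar_num(y_max, "y_max")
  if (y_max <= y_min) stopf("`y_max` must be strictly greater than `y_min`")
  structure(list(y_min = y_min, y_max = y_max), class = "normalizer")
}

#' @export
print.normalizer <- function(x, ...) {
  cat(sprintf("<normalizer> [%.4g, %.4g] mm -> [0, 1]\n", x$y_min, x$y_max))
  invisible(x)
}

#' Fit a min-max normalizer to a sample vector
#'
#' @param samples Numeric vector (length >= 2) with `max > min`; a constant
#'   sequence is rejected because its range cannot be rescaled.
#' @return A [normalizer()].
#' @export
fit_normalizer <- function(samples) {
  if (inherits(samples, "breathing_signal")) samples <- samples$samples
  if (length(samples) < 2L) stopf("need at least 2 samples to fit a normalizer")
  if (!all(is.finite(samples))) stopf("samples must be finite")
  lo <- min(samples); hi <- max(samples)
  if (hi == lo) stopf("constant sequence: range is zero, cannot normalize")
  normalizer(lo, hi)
}

#' Normalize amplitudes to the fitted 0-1 range
#'
#' The map is affine and order-preserving; values outside the fitted range are
#' extended affinely (they fall outside \[0, 1\]) rather than clipped, and the
#' returned vector carries a logical `out_of_range` attribute flagging them.
#'
#' @param samples Numeric vector in mm.
#' @param norm A [normalizer()].
#' @return Numeric vector in normalized units.
#' @export
normalize <- function(samples, norm) {
  if (!inherits(norm, "normalizer")) stopf("`norm` must be a normalizer")
  z <- (samples - norm$y_min) / (norm$y_max - norm$y_min)
  oor <- z < 0 | z > 1
  if (any(oor)) attr(z, "out_of_range") <- oor
  z
}

#' Invert [normalize()] back to mm
#'
#' @param samples Numeric vector in normalized units.
#' @param norm A [normalizer()].
#' @return Numeric vector in mm.
#' @export
denormalize <- function(samples, norm) {
  if (!inherits(norm, "normalizer")) stopf("`norm` must be a normalizer")
  as.numeric(samples) * (norm$y_max - norm$y_min) + norm$y_min
}
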