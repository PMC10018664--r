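#' Breathing pattern parameter set
#'
#' Parameters of the Lujan-type breathing-cycle model used by the simulator:
#' a baseline offset plus a per-cycle-scaled \eqn{\cos^{2n}} cycle profile,
#' linear baseline drift and additive Gaussian sensor noise. Each breathing
#' cycle draws its own period and amplitude from jittered distributions, so
#' cycle-to-cycle variability is smooth (jitter acts per cycle, never per
#' sample) and the phase is continuous across cycle boundaries.
#'
#' @param period_s Seconds per breathing cycle (> 0).
#' @param amplitude_mm Peak-to-trough excursion in mm (>= 0).
#' @param shape_exponent Positive integer n of the \eqn{\cos^{2n}} profile;
#'   larger n gives longer, flatter exhale plateaus.
#' @param period_jitter_frac Fractional SD of the per-cycle period, in
#'   \[0, 0.5\].
#' @param amplitude_jitter_frac Fractional SD of the per-cycle amplitude, in
#'   \[0, 0.5\].
#' @param drift_mm_per_min Linear baseline drift rate (mm per minute).
#' @param noise_sd_mm SD of additive Gaussian sensor noise (mm, >= 0).
#' @param baseline_mm Resting (end-exhale) offset in mm.
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(period_s, amplitude_mm, shape_exponent = 2L,
                           period_jitter_frac = 0, amplitude_jitter_frac = 0,
                           drift_mm_per_min = 0, noise_sd_mm = 0,
                           baseline_mm = 0) {
  assert_scalar_num(period_s, "period_s", positive = TRUE)
  assert_scalar_num(amplitude_mm, "amplitude_mm", nonneg = TRUE)
  assert_scalar_num(shape_exponent, "shape_exponent")
  if (shape_exponent < 1 || shape_exponent != round(shape_exponent))
    stopf("`shape_exponent` must be a positive integer")
  for (j in c("period_jitter_frac", "amplitude_jitter_frac")) {
    v <- get(j)
    assert_scalar_num(v, j, nonneg = TRUE)
    if (v > 0.5) stopf("`%s` must be in [0, 0.5]", j)
  }
  assert_scalar_num(drift_mm_per_min, "drift_mm_per_min")
  assert_scalar_num(noise_sd_mm, "noise_sd_mm", nonneg = TRUE)
  assert_scalar_num(baseline_mm, "baseline_mm")
  structure(list(
    period_s = period_s, amplitude_mm = amplitude_mm,
    shape_exponent = as.integer(shape_exponent),
    period_jitter_frac = period_jitter_frac,
    amplitude_jitter_frac = amplitude_jitter_frac,
    drift_mm_per_min = drift_mm_per_min,
    noise_sd_mm = noise_sd_mm, baseline_mm = baseline_mm
  ), class = "pattern_params")
}

#' @export
print.pattern_params <- function(x, ...) {
  cat(sprintf(
    "<pattern_params> period %.2f s, amplitude %.1f mm, cos^%d profile\n",
    x$period_s, x$amplitude_mm, 2L * x$shape_exponent))
  cat(sprintf("  jitter: period %.0f%%, amplitude %.0f%% | drift %.2f mm/min | noise SD %.2f mm | baseline %.1f mm\n",
              100 * x$period_jitter_frac, 100 * x$amplitude_jitter_frac,
              x$drift_mm_per_min, x$noise_sd_mm, x$baseline_mm))
  invisible(x)
}

#' The five qualitative breathing regimes
#'
#' @return Character vector of the five regime names.
#' @export
breathing_patterns <- function() {
  c("steady", "slow_deep", "slow_shallow", "rapid_deep", "rapid_shallow")
}

# Documented preset constants. "Slow" ~ 5 s cycles, "rapid" ~ 2.5 s,
# "deep" ~ 15 mm excursion, "shallow" ~ 5 mm, bracketing typical
# thoraco-abdominal excursions; steady is the idealised jitter-free,
# drift-free, noise-free 4 s / 10 mm regular breather.
.pattern_preset_table <- list(
  steady        = list(period_s = 4.0, amplitude_mm = 10, period_jitter_frac = 0,
                       amplitude_jitter_frac = 0, drift_mm_per_min = 0,
                       noise_sd_mm = 0),
  slow_deep     = list(period_s = 5.0, amplitude_mm = 15, period_jitter_frac = 0.08,
                       amplitude_jitter_frac = 0.10, drift_mm_per_min = 0.30,
                       noise_sd_mm = 0.10),
  slow_shallow  = list(period_s = 5.0, amplitude_mm = 5, period_jitter_frac = 0.08,
                       amplitude_jitter_frac = 0.10, drift_mm_per_min = -0.20,
                       noise_sd_mm = 0.10),
  rapid_deep    = list(period_s = 2.5, amplitude_mm = 15, period_jitter_frac = 0.10,
                       amplitude_jitter_frac = 0.12, drift_mm_per_min = 0.25,
                       noise_sd_mm = 0.10),
  rapid_shallow = list(period_s = 2.5, amplitude_mm = 5, period_jitter_frac = 0.10,
                       amplitude_jitter_frac = 0.12, drift_mm_per_min = -0.15,
                       noise_sd_mm = 0.10)
)

#' Preset parameters for a named breathing regime
#'
#' Encodes the five qualitative regimes (steady; slow/rapid crossed with
#' increased/shallow depth) as fixed, documented simulator constants.
#' "Rapid" presets have strictly shorter cycle periods than "slow" presets,
#' "deep" presets strictly larger excursions than "shallow" presets, and the
#' steady preset has zero cycle-to-cycle jitter, drift and noise.
#'
#' @param kind One of [breathing_patterns()].
#' @return A [pattern_params()] object.
#' @export
#' @examples
#' pattern_presets("steady")
pattern_presets <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% breathing_patterns())
    stopf("`kind` must be one of: %s", paste(breathing_patterns(), collapse = ", "))
  do.call(pattern_params, c(.pattern_preset_table[[kind]],
                            list(shape_exponent = 2L, baseline_mm = 0)))
}

#' Dump the regime presets as a human-readable YAML block
#'
#' Writes (or returns) the preset table so simulated experiments are
#' self-documenting.
#'
#' @param path Optional file path; if `NULL` the YAML text is returned.
#' @return The YAML string, invisibly when written to `path`.
#' @export
write_pattern_presets <- function(path = NULL) {
  txt <- yaml::as.yaml(.pattern_preset_table)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Breathing signal container
#'
#' A uniformly sampled scalar breathing-amplitude trace (mm), as recorded by
#' an external optical marker.
#'
#' @param samples Numeric vector of amplitudes (mm); length >= 2, all finite.
#' @param sampling_rate_hz Samples per second (> 0).
#' @param signal_id Opaque label.
#' @param pattern Optional regime label (one of [breathing_patterns()]).
#' @return An object of class `breathing_signal`.
#' @export
breathing_signal <- function(samples, sampling_rate_hz, signal_id = "signal",
                             pattern = NULL) {
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stopf("a breathing signal needs at least 2 samples")
  if (!all(is.finite(samples))) stopf("all samples must be finite")
  if (!is.null(pattern) && !pattern %in% breathing_patterns())
    stopf("unknown pattern label '%s'", pattern)
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 signal_id = as.character(signal_id), pattern = pattern),
            class = "breathing_signal")
}

#' @export
print.breathing_signal <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate_hz
  cat(sprintf("<breathing_signal> '%s': %d samples @ %.3g Hz (%.1f s)%s\n",
              x$signal_id, length(x$samples), x$sampling_rate_hz, dur,
              if (is.null(x$pattern)) "" else paste0(", pattern ", x$pattern)))
  cat(sprintf("  range [%.2f, %.2f] mm\n", min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.breathing_signal <- function(x) length(x$samples)

# Closed-form noiseless cycle profile on an arbitrary time grid, given the
# cycle boundary times and per-cycle amplitudes. Each cycle maps its local
# time u in [0,1) to cos^(2n)(pi/2 + pi*u): 0 at both cycle edges (troughs),
# peaking at amplitude mid-cycle, hence continuous across cycles even when
# consecutive amplitudes differ.
.cycle_profile <- function(t, cycle_starts, cycle_periods, cycle_amps, n) {
  k <- findInterval(t, cycle_starts)
  k[k < 1L] <- 1L
  k[k > length(cycle_periods)] <- length(cycle_periods)
  u <- (t - cycle_starts[k]) / cycle_periods[k]
  cycle_amps[k] * cos(pi / 2 + pi * u)^(2L * n)
}

#' Simulate a breathing trace
#'
#' Generates `round(duration_s * fs)` samples of
#' `baseline + drift * t + A_k * cos^(2n)(phase)` plus Gaussian noise, where
#' each cycle k draws its own period and amplitude
#' (`N(period_s, period_jitter_frac * period_s)` etc., truncated to stay
#' positive). A pure function of `(params, duration_s, fs, seed)`: the same
#' arguments always return the identical trace, and the caller's RNG state is
#' left untouched. Cycle randomness is drawn before sample noise, so zeroing
#' `noise_sd_mm` with the same seed reproduces the same underlying cycles.
#'
#' @param params A [pattern_params()] object.
#' @param duration_s Trace duration in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0); the recording default is 26 Hz.
#' @param seed Integer seed.
#' @param signal_id,pattern Passed to [breathing_signal()].
#' @return A [breathing_signal()].
#' @export
#' @examples
#' sig <- generate_breathing(pattern_presets("steady"), duration_s = 60,
#'                           fs = 26, seed = 1)
#' length(sig$samples)  # 1560
generate_breathing <- function(params, duration_s, fs = 26, seed = 1,
                               signal_id = "sim", pattern = NULL) {
  if (!inherits(params, "pattern_params")) stopf("`params` must be pattern_params")
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  n_samp <- round(duration_s * fs)
  if (n_samp < 2L) stopf("duration_s * fs must give at least 2 samples")
  t <- (seq_len(n_samp) - 1L) / fs

  with_seed(seed, {
    # draw cycles until they cover the trace (cap protects against tiny periods)
    n_guess <- ceiling(duration_s / params$period_s) + 10L
    periods <- amps <- numeric(0)
    total <- 0
    while (total < duration_s) {
      p <- stats::rnorm(n_guess, params$period_s,
                        params$period_jitter_frac * params$period_s)
      p <- pmax(p, 0.25 * params$period_s)
      a <- stats::rnorm(n_guess, params$amplitude_mm,
                        params$amplitude_jitter_frac * params$amplitude_mm)
      a <- pmax(a, 0)
      periods <- c(periods, p); amps <- c(amps, a)
      total <- sum(periods)
    }
    starts <- cumsum(c(0, periods[-length(periods)]))
    y <- params$baseline_mm + (params$drift_mm_per_min / 60) * t +
      .cycle_profile(t, starts, periods, amps, params$shape_exponent)
    if (params$noise_sd_mm > 0)
      y <- y + stats::rnorm(n_samp, 0, params$noise_sd_mm)
    breathing_signal(y, fs, signal_id = signal_id, pattern = pattern)
  })
}

#' Simulate a cohort of breathing traces
#'
#' Draws `n_signals` traces whose regime labels follow `mix` (largest-remainder
#' rounding of the requested fractions) and whose durations are uniform in
#' `duration_range_s`. The default duration range, 1380-3600 s, matches
#' clinical tracking recordings of 23-60 minutes.
#'
#' @param n_signals Number of traces (>= 1).
#' @param mix Named numeric vector or list mapping regime name to fraction;
#'   fractions must be non-negative and sum to 1 (tolerance 1e-6).
#' @param duration_range_s Length-2 numeric `(min, max)` duration in seconds.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return List of [breathing_signal()] objects with `pattern` labels set.
#' @export
generate_cohort <- function(n_signals, mix, duration_range_s = c(1380, 3600),
                            fs = 26, seed = 1) {
  if (!is.numeric(n_signals) || n_signals < 1) stopf("`n_signals` must be >= 1")
  n_signals <- as.integer(n_signals)
  mix <- unlist(mix)
  if (length(mix) == 0L) stopf("`mix` must not be empty")
  if (any(mix < 0)) stopf("`mix` fractions must be non-negative")
  if (is.null(names(mix)) || any(!nzchar(names(mix))))
    stopf("`mix` must be named by breathing pattern")
  if (!all(names(mix) %in% breathing_patterns()))
    stopf("unknown pattern in `mix`: %s",
          paste(setdiff(names(mix), breathing_patterns()), collapse = ", "))
  if (abs(sum(mix) - 1) > 1e-6) stopf("`mix` fractions must sum to 1")
  if (length(duration_range_s) != 2L || duration_range_s[1] <= 0 ||
      duration_range_s[2] < duration_range_s[1])
    stopf("`duration_range_s` must be (min, max) with 0 < min <= max")

  # largest-remainder apportionment of n_signals across regimes
  raw <- mix * n_signals
  counts <- floor(raw)
  rem <- n_signals - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  kinds <- rep(names(mix), counts)

  seeds <- derive_seeds(seed, n_signals + 1L)
  durations <- with_seed(seeds[n_signals + 1L],
                         stats::runif(n_signals, duration_range_s[1], duration_range_s[2]))
  lapply(seq_len(n_signals), function(i) {
    generate_breathing(pattern_presets(kinds[i]), durations[i], fs = fs,
                       seed = seeds[i],
                       signal_id = sprintf("sim_%03d_%s", i, kinds[i]),
                       pattern = kinds[i])
  })
}
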