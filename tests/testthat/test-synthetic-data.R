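test_that("regime presets encode the verbal breathing patterns as orderings", {
  expect_setequal(breathing_patterns(),
                  c("steady", "slow_deep", "slow_shallow", "rapid_deep", "rapid_shallow"))
  st <- pattern_presets("steady")
  expect_identical(st$period_jitter_frac, 0)
  expect_identical(st$amplitude_jitter_frac, 0)
  # rapid strictly faster than slow, deep strictly larger than shallow
  expect_lt(pattern_presets("rapid_deep")$period_s, pattern_presets("slow_deep")$period_s)
  expect_lt(pattern_presets("rapid_shallow")$period_s, pattern_presets("slow_shallow")$period_s)
  expect_gt(pattern_presets("slow_deep")$amplitude_mm, pattern_presets("slow_shallow")$amplitude_mm)
  expect_gt(pattern_presets("rapid_deep")$amplitude_mm, pattern_presets("rapid_shallow")$amplitude_mm)
  expect_error(pattern_presets("walking"), "one of")
})

test_that("parameter invariants are enforced", {
  expect_error(pattern_params(period_s = 0, amplitude_mm = 10), "> 0")
  expect_error(pattern_params(4, -1), ">=")
  expect_error(pattern_params(4, 10, shape_exponent = 0.5), "positive integer")
  expect_error(pattern_params(4, 10, period_jitter_frac = 0.6), "0.5")
  expect_error(generate_breathing(pattern_presets("steady"), duration_s = -5), "> 0")
  expect_error(generate_breathing(pattern_presets("steady"), 60, fs = 0), "> 0")
})

test_that("trace length, determinism and sample finiteness hold", {
  sig <- generate_breathing(pattern_presets("steady"), duration_s = 60, fs = 26, seed = 7)
  expect_s3_class(sig, "breathing_signal")
  expect_identical(length(sig$samples), 1560L)  # 60 s x 26 Hz
  expect_true(all(is.finite(sig$samples)))
  sig2 <- generate_breathing(pattern_presets("steady"), duration_s = 60, fs = 26, seed = 7)
  expect_identical(sig$samples, sig2$samples)
  sig3 <- generate_breathing(pattern_presets("rapid_deep"), 60, fs = 26, seed = 7)
  sig4 <- generate_breathing(pattern_presets("rapid_deep"), 60, fs = 26, seed = 8)
  expect_false(identical(sig3$samples, sig4$samples))
})

test_that("with stochastic terms zeroed the trace equals the closed-form profile", {
  p <- pattern_params(period_s = 4, amplitude_mm = 10, shape_exponent = 2L)
  sig <- generate_breathing(p, duration_s = 40, fs = 26, seed = 1)
  expect_equal(sig$samples, profile_oracle(p, 40, 26), tolerance = 1e-12)
  # extrema: min exactly 0 at cycle edges; max within one sample step of the peak
  expect_gte(min(sig$samples), -1e-12)
  expect_lte(min(sig$samples), 1e-12)
  expect_lte(max(sig$samples), 10 + 1e-12)
  expect_gte(max(sig$samples), max(profile_oracle(p, 40, 26)) - 1e-12)
  # a higher shape exponent narrows the inhale peak
  p4 <- pattern_params(4, 10, shape_exponent = 4L)
  sig4 <- generate_breathing(p4, 40, fs = 26, seed = 1)
  expect_lt(mean(sig4$samples), mean(sig$samples))
})

test_that("mean cycle length from zero crossings recovers the period", {
  for (kind in c("steady", "rapid_deep")) {
    p <- pattern_presets(kind)
    p$period_jitter_frac <- 0; p$amplitude_jitter_frac <- 0
    p$noise_sd_mm <- 0; p$drift_mm_per_min <- 0
    sig <- generate_breathing(p, duration_s = 120, fs = 26, seed = 2)
    x <- sig$samples - mean(sig$samples)
    up <- which(x[-1] > 0 & x[-length(x)] <= 0)   # upward mean crossings
    est <- mean(diff(up)) / 26
    expect_lt(abs(est - p$period_s) / p$period_s, 0.05)
  }
})

test_that("residual SD against the same-seed noiseless trace recovers noise_sd_mm", {
  p <- pattern_presets("slow_deep")
  p$noise_sd_mm <- 0.25
  noisy <- generate_breathing(p, duration_s = 90, fs = 26, seed = 13)
  p0 <- p; p0$noise_sd_mm <- 0
  clean <- generate_breathing(p0, duration_s = 90, fs = 26, seed = 13)
  est <- sd(noisy$samples - clean$samples)
  expect_lt(abs(est - 0.25) / 0.25, 0.10)
})

test_that("cohort counts, labels, durations and reproducibility follow the mix", {
  sigs <- generate_cohort(10, c(steady = 1.0), duration_range_s = c(30, 60), seed = 1)
  expect_length(sigs, 10L)
  expect_true(all(vapply(sigs, `[[`, "", "pattern") == "steady"))

  sigs <- generate_cohort(5, c(steady = 0.4, rapid_deep = 0.6),
                          duration_range_s = c(30, 60), seed = 2)
  counts <- table(vapply(sigs, `[[`, "", "pattern"))
  expect_identical(as.integer(counts[c("steady", "rapid_deep")]), c(2L, 3L))

  durs <- vapply(sigs, function(s) length(s$samples) / s$sampling_rate_hz, numeric(1))
  expect_true(all(durs >= 30 - 1 / 26 & durs <= 60 + 1 / 26))

  again <- generate_cohort(5, c(steady = 0.4, rapid_deep = 0.6),
                           duration_range_s = c(30, 60), seed = 2)
  expect_identical(lapply(sigs, `[[`, "samples"), lapply(again, `[[`, "samples"))

  expect_error(generate_cohort(5, c(steady = 0.5), duration_range_s = c(30, 60)), "sum to 1")
  expect_error(generate_cohort(5, c(steady = 1.5, rapid_deep = -0.5)), "non-negative")
  expect_error(generate_cohort(5, list()), "empty")
})

test_that("preset YAML dump is parseable and complete", {
  txt <- write_pattern_presets()
  parsed <- yaml::yaml.load(txt)
  expect_setequal(names(parsed), breathing_patterns())
  expect_identical(parsed$steady$period_s, 4.0)
})
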