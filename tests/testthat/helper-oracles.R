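# Independent brute-force oracles the fast implementations are checked against.

brute_rmse <- function(Y, Yhat) {
  s <- 0
  for (i in seq_along(Y)) s <- s + (Y[i] - Yhat[i])^2
  sqrt(s / length(Y))
}

brute_mae <- function(Y, Yhat) {
  s <- 0
  for (i in seq_along(Y)) s <- s + abs(Y[i] - Yhat[i])
  s / length(Y)
}

brute_nrmse <- function(Y, Yhat) brute_rmse(Y, Yhat) / (max(Y) - min(Y))

# count supervised pairs by explicit enumeration of every candidate window
brute_pair_count <- function(L, W, O, h) {
  n <- 0L
  for (i in seq_len(L)) {
    in_end <- i + W - 1L
    tg_start <- in_end + h
    tg_end <- tg_start + O - 1L
    if (tg_end <= L) n <- n + 1L
  }
  n
}

# closed-form noiseless jitter-free cycle profile on the sample grid
profile_oracle <- function(params, duration_s, fs) {
  t <- (seq_len(round(duration_s * fs)) - 1L) / fs
  u <- (t %% params$period_s) / params$period_s
  params$baseline_mm + params$drift_mm_per_min / 60 * t +
    params$amplitude_mm * cos(pi / 2 + pi * u)^(2 * params$shape_exponent)
}

# short deterministic test signal: jitter-free breathing plus known extras
toy_signal <- function(duration_s = 60, fs = 26, seed = 1,
                       kind = "steady") {
  generate_breathing(pattern_presets(kind), duration_s, fs = fs, seed = seed,
                     pattern = kind)
}

tiny_sets <- function(n = 120, W = 10L, O = 1L, h = 1L, seed = 4) {
  x <- with_fixed_seed(seed, cumsum(rnorm(n, 0, 0.05)) + sin(seq_len(n) / 4))
  norm <- fit_normalizer(x)
  make_supervised(normalize(x, norm), window_spec(W, O, h))
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
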