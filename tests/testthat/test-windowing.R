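test_that("chronological split matches the 35/5/60 partition exactly", {
  segs <- split_signal(sin(1:1000), split_spec(0.35, 0.05, 0.60))
  expect_identical(lengths(segs), c(train = 350L, val = 50L, test = 600L))
  # partition property: concatenation restores the signal
  expect_identical(unname(unlist(segs)), sin(1:1000))
})

test_that("tiny inputs floor the validation segment to empty with a warning", {
  expect_warning(segs <- split_signal(1:10, split_spec(0.35, 0.05, 0.60)),
                 "validation segment is empty")
  expect_identical(lengths(segs), c(train = 3L, val = 0L, test = 7L))
  expect_identical(unname(unlist(segs)), as.numeric(1:10))
})

test_that("split fractions are validated", {
  expect_error(split_spec(0.5, 0.5, 0.5), "sum to 1")
  expect_error(split_spec(-0.1, 0.5, 0.6), ">=")
  expect_error(split_signal(1:2, split_spec()), "at least 3")
})

test_that("supervised pairs follow the latency-shifted windowing contract", {
  s <- 0:9  # 0-based values make index arithmetic transparent
  set <- make_supervised(s, window_spec(3L, 1L, 1L))
  expect_identical(n_pairs(set), 7L)
  expect_identical(set$inputs[1, ], c(0, 1, 2))
  expect_identical(set$targets[1, 1], 3)
  expect_identical(set$targets[7, 1], 9)

  set2 <- make_supervised(s, window_spec(3L, 1L, 2L))
  expect_identical(n_pairs(set2), 6L)
  expect_identical(set2$targets[1, 1], 4)

  set3 <- make_supervised(0:4, window_spec(5L, 1L, 1L))
  expect_identical(n_pairs(set3), 0L)
  expect_identical(set3$status, "insufficient_length")

  setO <- make_supervised(s, window_spec(2L, 3L, 2L))
  expect_identical(set$spec$input_len, 3L)
  expect_identical(setO$inputs[1, ], c(0, 1))
  expect_identical(setO$targets[1, ], c(3, 4, 5))
})

test_that("pair count formula equals exhaustive enumeration over the whole small grid", {
  for (L in c(1:12, 20L, 33L, 40L)) {
    x <- seq_len(L)
    for (W in 1:8) for (O in 1:8) for (h in 1:8) {
      expected <- brute_pair_count(L, W, O, h)
      set <- make_supervised(x, window_spec(W, O, h))
      expect_identical(n_pairs(set), expected)
      expect_identical(n_pairs(set), max(0L, L - W - h - O + 2L))
    }
  }
})

test_that("h=1, O=1 targets tile the sequence past the first window (coverage)", {
  x <- cumsum(runif(60))
  set <- make_supervised(x, window_spec(7L, 1L, 1L))
  rebuilt <- c(set$inputs[1, ], as.numeric(set$targets))
  expect_identical(rebuilt, x)
})

test_that("latency in milliseconds maps to a sample horizon with floor 1", {
  expect_identical(latency_to_samples(115, 26), 3L)     # 2.99 rounds up
  expect_identical(latency_to_samples(38.46, 26), 1L)   # ~1.0 samples
  expect_identical(latency_to_samples(0, 26), 1L)       # always >= one step ahead
  expect_identical(latency_to_samples(500, 26), 13L)
  expect_error(latency_to_samples(-1, 26), ">=")
})

test_that("supervised sets export to the two-file delimited layout", {
  set <- make_supervised(sin(1:40), window_spec(5L, 2L, 1L))
  stem <- tempfile()
  paths <- export_supervised(set, stem)
  back_in <- as.matrix(utils::read.csv(paste0(stem, "_inputs.csv")))
  back_tg <- as.matrix(utils::read.csv(paste0(stem, "_targets.csv")))
  expect_equal(unname(back_in), unname(set$inputs), tolerance = 1e-12)
  expect_equal(unname(back_tg), unname(set$targets), tolerance = 1e-12)
})

test_that("window_spec validates its geometry", {
  expect_error(window_spec(0L), ">= 1")
  expect_error(window_spec(5L, 0L), ">= 1")
  expect_error(window_spec(5L, 1L, 0L), ">= 1")
  expect_error(make_supervised(1:10, list(input_len = 3)), "window_spec")
})
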