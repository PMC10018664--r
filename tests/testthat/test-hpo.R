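test_that("the search space reproduces the tuning-table domains", {
  sp <- default_search_space()
  expect_identical(sp$units$values, c(3L, 5L, 10L, 20L, 30L, 40L, 50L, 60L))
  expect_identical(sp$n_layers$values, c(1L, 2L, 3L, 5L))
  expect_length(sp$optimizer$values, 8L)
  # printed learning-rate row repeats 0.005; deduplicated to 6 unique values
  expect_identical(sp$learning_rate$values, c(0.0001, 0.005, 0.001, 0.003, 0.05, 0.01))
  expect_length(sp$learning_rate$values, 6L)
  expect_identical(sp$latency$values, c(1L, 5L, 10L, 15L))
  expect_identical(sp$batch_size$values, c(50L, 100L, 150L, 200L, 250L, 300L, 400L, 500L))
  expect_identical(sp$epochs$values, c(125L, 250L, 500L, 1000L, 2000L))
  expect_identical(sp$input_window$values, c(1L, 5L, 10L, 20L, 30L, 50L, 100L))
  expect_identical(sp$output_window$values, c(1L, 3L, 5L, 10L))
  expect_length(sp$hidden_activation$values, 11L)
  expect_length(sp$output_activation$values, 4L)
  expect_length(sp$loss$values, 4L)
  expect_length(sp$multistep$values, 2L)
  expect_error(param_domain("x", integer(0)), "no values")
  expect_error(param_domain("x", c(1, 1, 2)), "duplicate")
})

test_that("the default plan covers every hyperparameter and is internally valid", {
  plan <- default_plan()
  expect_identical(plan$repeats, 10L)
  grouped <- unique(unlist(lapply(plan$groups, `[[`, "params")))
  expect_setequal(union(grouped, names(plan$base_config)), names(plan$space))
  # named pairings in order: A loss+optimizer grid, B optimizer+lr random, C layers+units grid
  expect_identical(plan$groups$A$params, c("loss", "optimizer"))
  expect_identical(plan$groups$A$method, "grid")
  expect_identical(plan$groups$B$params, c("optimizer", "learning_rate"))
  expect_identical(plan$groups$B$method, "random")
  expect_identical(plan$groups$C$params, c("n_layers", "units"))
  expect_identical(plan$groups$C$method, "grid")
  expect_error(hpo_plan(list(search_group("loss", "grid")), list()), "neither")
})

test_that("grid groups evaluate the full cross-product once per seed", {
  space <- list(a = param_domain("a", c(1, 2)), b = param_domain("b", c("x", "y")))
  calls <- new.env(); calls$log <- list()
  obj <- function(config, seed) {
    calls$log[[length(calls$log) + 1L]] <- c(config$a, config$b, seed)
    abs(config$a - 2) + (config$b != "y")
  }
  res <- run_group(search_group(c("a", "b"), "grid"), list(a = 1, b = "x"),
                   obj, seeds = c(1, 2), space = space)
  expect_identical(nrow(res$ledger), 8L)          # 4 configs x 2 seeds
  expect_length(calls$log, 8L)
  expect_identical(res$winner, list(a = 2, b = "y"))
  # ledger completeness: each config appears exactly once per seed
  expect_true(all(table(res$ledger$config_id, res$ledger$seed) == 1L))
})

test_that("a rigged objective on the layers-units group recovers the planted optimum", {
  obj <- function(config, seed) abs(config$units - 10) + abs(config$n_layers - 3)
  res <- run_group(search_group(c("n_layers", "units"), "grid"),
                   default_plan()$base_config, obj, seeds = 1:3)
  expect_identical(res$winner$n_layers, 3L)
  expect_identical(res$winner$units, 10L)
  expect_identical(nrow(res$ledger), 32L * 3L)
})

test_that("random groups sample distinct configurations reproducibly", {
  space <- list(a = param_domain("a", 1:6), b = param_domain("b", 1:8))
  obj <- function(config, seed) config$a + config$b
  g <- search_group(c("a", "b"), "random", budget = 5L)
  r1 <- run_group(g, list(a = 1, b = 1), obj, seeds = 1L, space = space, sample_seed = 11)
  r2 <- run_group(g, list(a = 1, b = 1), obj, seeds = 1L, space = space, sample_seed = 11)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(nrow(r1$ledger), 5L)
  expect_false(any(duplicated(r1$ledger[, c("a", "b")])))
  r3 <- run_group(g, list(a = 1, b = 1), obj, seeds = 1L, space = space, sample_seed = 12)
  expect_false(identical(r1$ledger$a, r3$ledger$a) && identical(r1$ledger$b, r3$ledger$b))
  # budget larger than the product is capped
  g2 <- search_group(c("a", "b"), "random", budget = 100L)
  r4 <- run_group(g2, list(a = 1, b = 1), obj, seeds = 1L, space = space)
  expect_identical(nrow(r4$ledger), 48L)
})

test_that("ties break to the first configuration in domain enumeration order", {
  space <- list(a = param_domain("a", c(5, 1, 3)))
  obj <- function(config, seed) 7   # everything ties
  res <- run_group(search_group("a", "grid"), list(a = 0), obj, 1L, space = space)
  expect_identical(res$winner$a, 5)
})

test_that("diverged trials score +Inf and an all-failed group aborts the plan", {
  space <- list(a = param_domain("a", 1:2), b = param_domain("b", 1:2))
  obj_half <- function(config, seed)
    if (config$a == 1) list(objective = Inf, status = "diverged") else config$b
  res <- run_group(search_group(c("a", "b"), "grid"), list(a = 1, b = 1),
                   obj_half, 1L, space = space)
  expect_identical(res$winner, list(a = 2L, b = 1L))
  expect_identical(sum(res$ledger$status == "diverged"), 2L)

  plan <- hpo_plan(list(g1 = search_group("a", "grid"), g2 = search_group("b", "grid")),
                   base_config = list(a = 1L, b = 1L), repeats = 2L, space = space)
  all_fail <- function(config, seed) stop("boom")
  out <- run_plan(plan, all_fail)
  expect_identical(out$status, "aborted")
  expect_null(out$best)
  expect_identical(nrow(out$ledger), 4L)   # first group's ledger kept intact
  expect_true(all(out$ledger$status == "diverged"))
})

test_that("run_plan resolves groups in order, freezes winners and recovers a separable optimum", {
  plan <- default_plan(repeats = 2L)
  plan$groups <- plan$groups[c("A", "B", "C")]
  target <- list(loss = "Huber", optimizer = "RMSprop", learning_rate = 0.003,
                 n_layers = 3L, units = 30L)
  obj <- function(config, seed) {
    (config$loss != target$loss) + (config$optimizer != target$optimizer) +
      abs(log10(config$learning_rate / target$learning_rate)) +
      abs(config$n_layers - target$n_layers) + abs(config$units - target$units) / 10
  }
  out <- run_plan(plan, obj)
  expect_identical(out$status, "ok")
  for (nm in names(target)) expect_identical(out$best[[nm]], target[[nm]])
  # frozen optimizer: group B only searched the 6 learning rates
  expect_identical(out$n_trials, (32L + 6L + 32L) * 2L)
  expect_identical(as.integer(table(out$ledger$group)[c("A", "B", "C")]),
                   c(64L, 12L, 64L))
  # untouched hyperparameters keep their base values
  expect_identical(out$best$multistep, plan$base_config$multistep)
  # reproducibility: identical plan and seeds give an identical ledger
  out2 <- run_plan(plan, obj)
  expect_identical(out$ledger, out2$ledger)
})

test_that("trial ledgers export as one delimited row per trial", {
  space <- list(a = param_domain("a", 1:3))
  res <- run_group(search_group("a", "grid"), list(a = 1), function(c, s) c$a,
                   seeds = 1:2, space = space)
  path <- tempfile(fileext = ".tsv")
  write_ledger(res$ledger, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 6L)
  expect_true(all(c("config_id", "seed", "objective", "status", "a") %in% names(back)))
})

test_that("the training objective scores a real configuration and fails soft", {
  sig <- toy_signal(duration_s = 60, kind = "steady")
  obj <- make_training_objective(sig, "gru", epochs_override = 3L)
  cfg <- default_plan()$base_config
  cfg$input_window <- 10L
  res <- obj(cfg, seed = 1)
  expect_identical(res$status, "ok")
  expect_true(is.finite(res$objective) && res$objective >= 0)
  # an impossible geometry is a diverged trial, not an error
  cfg$input_window <- 100000L
  res2 <- obj(cfg, seed = 1)
  expect_identical(res2$status, "diverged")
  expect_identical(res2$objective, Inf)
})
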