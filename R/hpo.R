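#' Hyperparameter domain
#'
#' @param name Hyperparameter identifier.
#' @param values Finite, non-empty, duplicate-free ordered candidate list.
#' @return An object of class `param_domain`.
#' @export
param_domain <- function(name, values) {
  if (!is.character(name) || length(name) != 1L) stopf("`name` must be a string")
  if (length(values) == 0L) stopf("domain '%s' has no values", name)
  if (anyDuplicated(values)) stopf("domain '%s' has duplicate values", name)
  structure(list(name = name, values = values), class = "param_domain")
}

#' The full search space
#'
#' One domain per tunable hyperparameter, with the candidate lists used by the
#' grouped search. The learning-rate list is printed in the source table with
#' 0.005 appearing twice; it is deduplicated here to 6 unique values. The
#' "latency" domain is a horizon in samples (1, 5, 10, 15); use
#' [latency_to_samples()] to map a hardware latency in milliseconds onto it
#' (115 ms at 26 Hz is 3 samples). Hidden- and output-layer activations are
#' separate domains here (13 in total) even though study summaries count them
#' as a single "activation" variant.
#'
#' @return Named list of [param_domain()] objects.
#' @export
default_search_space <- function() {
  doms <- list(
    param_domain("n_layers", c(1L, 2L, 3L, 5L)),
    param_domain("units", c(3L, 5L, 10L, 20L, 30L, 40L, 50L, 60L)),
    param_domain("optimizer", optimizer_names()),
    param_domain("learning_rate", c(0.0001, 0.005, 0.001, 0.003, 0.05, 0.01)),
    param_domain("hidden_activation", names(.hidden_activations)),
    param_domain("output_activation", names(.output_activations)),
    param_domain("epochs", c(125L, 250L, 500L, 1000L, 2000L)),
    param_domain("latency", c(1L, 5L, 10L, 15L)),
    param_domain("batch_size", c(50L, 100L, 150L, 200L, 250L, 300L, 400L, 500L)),
    param_domain("loss", loss_names()),
    param_domain("input_window", c(1L, 5L, 10L, 20L, 30L, 50L, 100L)),
    param_domain("output_window", c(1L, 3L, 5L, 10L)),
    param_domain("multistep", c("encoder_decoder", "vector"))
  )
  stats::setNames(doms, vapply(doms, `[[`, "", "name"))
}

#' Search group
#'
#' One stage of the grouped search: 1-3 jointly searched hyperparameters and
#' the method resolving them.
#'
#' @param params Character vector of 1-3 hyperparameter names.
#' @param method `"grid"` (full cross-product) or `"random"` (uniform sampling
#'   without replacement).
#' @param budget Number of sampled configurations for `method = "random"`
#'   (ignored for grid; capped at the cross-product size).
#' @return An object of class `search_group`.
#' @export
search_group <- function(params, method = c("grid", "random"), budget = 10L) {
  method <- match.arg(method)
  if (!is.character(params) || length(params) < 1L || length(params) > 3L)
    stopf("`params` must name 1-3 hyperparameters")
  if (method == "random" && (!is.numeric(budget) || budget < 1))
    stopf("`budget` must be >= 1 for random search")
  structure(list(params = params, method = method, budget = as.integer(budget)),
            class = "search_group")
}

#' Grouped search plan
#'
#' An ordered list of [search_group()]s plus a complete default assignment;
#' groups are run in order, each group's winner overwriting the carried
#' assignment before the next group runs. A hyperparameter resolved by an
#' earlier group is frozen: later groups listing it search only their
#' still-unresolved parameters.
#'
#' @param groups Ordered list of [search_group()] objects.
#' @param base_config Named list assigning every hyperparameter a default.
#' @param repeats Trials (seeds) per configuration; objectives are averaged
#'   over them.
#' @param space Named list of [param_domain()]s (defaults to
#'   [default_search_space()]).
#' @return An object of class `hpo_plan`.
#' @export
hpo_plan <- function(groups, base_config, repeats = 10L,
                     space = default_search_space()) {
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "search_group")))
    stopf("`groups` must be a non-empty list of search_group objects")
  if (!is.numeric(repeats) || repeats < 1) stopf("`repeats` must be >= 1")
  gp <- unique(unlist(lapply(groups, `[[`, "params")))
  unknown <- setdiff(gp, names(space))
  if (length(unknown))
    stopf("group parameter(s) not in the search space: %s", paste(unknown, collapse = ", "))
  uncovered <- setdiff(names(space), union(gp, names(base_config)))
  if (length(uncovered))
    stopf("hyperparameter(s) in neither a group nor base_config: %s",
          paste(uncovered, collapse = ", "))
  structure(list(groups = groups, base_config = base_config,
                 repeats = as.integer(repeats), space = space),
            class = "hpo_plan")
}

#' Default grouped search plan
#'
#' Encodes the correlated pairings as ordered groups: A {loss, optimizer}
#' (grid), B {optimizer, learning rate} (random), C {layers, units} (grid),
#' then the remaining reported interactions — {epochs, learning rate},
#' {batch size, optimizer}, {latency, input window}, {hidden activation,
#' optimizer}, {multistep, epochs} — and singleton groups for the output
#' activation and output window. Parameters resolved early (the optimizer in
#' group A, the learning rate in B, the epochs in D) are frozen when they
#' reappear in later pairings. 10 trials per configuration by default.
#'
#' @param repeats Trials per configuration.
#' @return An [hpo_plan()].
#' @export
default_plan <- function(repeats = 10L) {
  groups <- list(
    A = search_group(c("loss", "optimizer"), "grid"),
    B = search_group(c("optimizer", "learning_rate"), "random", budget = 20L),
    C = search_group(c("n_layers", "units"), "grid"),
    D = search_group(c("epochs", "learning_rate"), "random", budget = 10L),
    E = search_group(c("batch_size", "optimizer"), "random", budget = 10L),
    F = search_group(c("latency", "input_window"), "grid"),
    G = search_group(c("hidden_activation", "optimizer"), "random", budget = 15L),
    H = search_group(c("multistep", "epochs"), "grid"),
    I = search_group("output_activation", "grid"),
    J = search_group("output_window", "grid")
  )
  base <- list(
    n_layers = 2L, units = 10L, optimizer = "Adam", learning_rate = 0.001,
    hidden_activation = "Tanh", output_activation = "Linear", epochs = 500L,
    latency = 1L, batch_size = 200L, loss = "MSE", input_window = 50L,
    output_window = 1L, multistep = "encoder_decoder"
  )
  hpo_plan(groups, base, repeats = repeats)
}

# enumerate the full cross-product of the given domains; the FIRST listed
# parameter varies fastest, so "first occurrence in domain order" tie-breaking
# is simply the first row.
.enumerate_grid <- function(domains) {
  vals <- lapply(domains, `[[`, "values")
  grid <- expand.grid(vals, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vapply(domains, `[[`, "", "name")
  grid
}

.coerce_trial <- function(res) {
  if (is.list(res)) {
    obj <- res$objective %||% Inf
    status <- res$status %||% (if (is.finite(obj)) "ok" else "diverged")
  } else {
    obj <- as.numeric(res)
    status <- if (is.finite(obj)) "ok" else "diverged"
  }
  if (!is.finite(obj)) obj <- Inf
  list(objective = obj, status = status)
}

#' Run one search group
#'
#' Evaluates candidate configurations (the full cross-product for grid, or
#' `budget` distinct uniformly sampled combinations for random search) on top
#' of the carried assignment, averaging the objective over `seeds`. Diverged
#' trials score +Inf. The winner is the lowest seed-averaged objective, ties
#' broken by first occurrence in domain enumeration order.
#'
#' @param group A [search_group()].
#' @param carried Named list: the full current assignment.
#' @param objective `function(config, seed)` returning a validation error in mm
#'   (or a list with `objective` and `status`).
#' @param seeds Integer vector of trial seeds.
#' @param space Named list of [param_domain()]s supplying the group's domains.
#' @param sample_seed Seed for the random-search draw.
#' @return List with `winner` (named list over the group's params, or NULL if
#'   unresolved), `status`, and `ledger` (one row per config x seed).
#' @export
run_group <- function(group, carried, objective, seeds,
                      space = default_search_space(), sample_seed = 1L) {
  if (!inherits(group, "search_group")) stopf("`group` must be a search_group")
  domains <- space[group$params]
  if (any(vapply(domains, is.null, TRUE)))
    stopf("group parameter(s) missing from the space")
  cand <- .enumerate_grid(domains)
  if (group$method == "random") {
    k <- min(group$budget, nrow(cand))
    pick <- with_seed(sample_seed, sort(sample.int(nrow(cand), k)))
    cand <- cand[pick, , drop = FALSE]
  }
  nc <- nrow(cand)
  rows <- vector("list", nc * length(seeds))
  avg <- numeric(nc)
  ri <- 0L
  for (ci in seq_len(nc)) {
    cfg <- carried
    for (p in group$params) cfg[[p]] <- cand[[p]][ci]
    objs <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      tr <- .coerce_trial(tryCatch(objective(cfg, seeds[si]),
                                   error = function(e) list(objective = Inf,
                                                            status = "diverged")))
      objs[si] <- tr$objective
      ri <- ri + 1L
      rows[[ri]] <- c(list(config_id = ci, seed = seeds[si],
                           objective = tr$objective, status = tr$status),
                      cfg)
    }
    avg[ci] <- mean(objs)
  }
  ledger <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (all(!is.finite(avg)))
    return(list(winner = NULL, status = "unresolved", ledger = ledger))
  wi <- which.min(avg)   # first minimum = first in enumeration order
  winner <- as.list(cand[wi, , drop = FALSE])
  names(winner) <- names(cand)
  list(winner = winner, status = "resolved", ledger = ledger)
}

#' Run a grouped search plan
#'
#' Runs the groups in order, freezing each group's winning values into the
#' carried assignment (a parameter resolved by an earlier group is not
#' re-searched when it reappears later). Returns the final assignment and the
#' complete trial ledger: every evaluated configuration appears exactly once
#' per seed, and the total trial count is the sum over groups of
#' (configurations x repeats). If every configuration of a group fails, the
#' plan aborts with the ledger accumulated so far intact.
#'
#' @param plan An [hpo_plan()].
#' @param objective `function(config, seed)` as in [run_group()].
#' @param seeds Trial seeds; defaults to `1:plan$repeats`.
#' @return List with `best` (full assignment), `status` (`"ok"` or
#'   `"aborted"`), `ledger` (data.frame with a `group` column), and
#'   `n_trials`.
#' @export
run_plan <- function(plan, objective, seeds = NULL) {
  if (!inherits(plan, "hpo_plan")) stopf("`plan` must be an hpo_plan")
  if (is.null(seeds)) seeds <- seq_len(plan$repeats)
  carried <- plan$base_config
  resolved <- character(0)
  ledgers <- list()
  gnames <- names(plan$groups) %||% as.character(seq_along(plan$groups))
  if (is.null(names(plan$groups))) names(plan$groups) <- gnames
  status <- "ok"
  for (gi in seq_along(plan$groups)) {
    g <- plan$groups[[gi]]
    free <- setdiff(g$params, resolved)
    if (!length(free)) next   # fully frozen by earlier winners
    eff <- search_group(free, g$method, max(1L, g$budget))
    res <- run_group(eff, carried, objective, seeds, space = plan$space,
                     sample_seed = seeds[1] + gi)
    if (nrow(res$ledger)) {
      res$ledger <- cbind(group = gnames[gi], res$ledger)
      ledgers[[length(ledgers) + 1L]] <- res$ledger
    }
    if (res$status == "unresolved") {
      status <- "aborted"
      break
    }
    for (p in names(res$winner)) carried[[p]] <- res$winner[[p]]
    resolved <- union(resolved, free)
  }
  ledger <- if (length(ledgers)) do.call(rbind, ledgers) else NULL
  list(best = if (status == "ok") carried else NULL, status = status,
       ledger = ledger, n_trials = if (is.null(ledger)) 0L else nrow(ledger))
}

#' Export a trial ledger as delimited text
#' @param ledger The `ledger` data.frame from [run_plan()] or [run_group()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Training-based search objective for one signal
#'
#' Builds the `function(config, seed)` objective the search plan needs: the
#' signal is split chronologically, the normalizer fitted on the training
#' segment, supervised sets built at the configuration's window geometry, the
#' model trained, and the seed's validation RMSE in mm returned. Any failure
#' (divergence, window too long for the segment) scores +Inf with status
#' `"diverged"`.
#'
#' @param signal A [breathing_signal()].
#' @param architecture One of [architectures()].
#' @param split A [split_spec()].
#' @param epochs_override If non-NULL, caps training epochs for desk-scale
#'   sweeps regardless of the configuration's `epochs` value.
#' @return `function(config, seed)` returning `list(objective, status)`.
#' @export
make_training_objective <- function(signal, architecture, split = split_spec(),
                                    epochs_override = NULL) {
  force(signal); force(architecture); force(split); force(epochs_override)
  function(config, seed) {
    tryCatch({
      spec <- model_spec(architecture, config$n_layers, config$units,
                         config$hidden_activation, config$output_activation,
                         multistep = config$multistep,
                         window = window_spec(config$input_window,
                                              config$output_window,
                                              config$latency))
      epochs <- if (is.null(epochs_override)) config$epochs else
        min(config$epochs, epochs_override)
      tc <- train_config(config$optimizer, config$learning_rate, epochs,
                         config$batch_size, config$loss, seed)
      segs <- split_signal(signal, split)
      norm <- fit_normalizer(segs$train)
      tr <- make_supervised(normalize(segs$train, norm), spec$window, "train")
      va <- make_supervised(normalize(segs$val, norm), spec$window, "val")
      if (n_pairs(tr) == 0L || n_pairs(va) == 0L)
        return(list(objective = Inf, status = "diverged"))
      fit <- train_predictor(spec, tr, va, tc)
      if (fit$status != "ok") return(list(objective = Inf, status = "diverged"))
      rep <- evaluate_split(fit, va, norm)
      list(objective = rep$rmse_mm, status = "ok")
    }, error = function(e) list(objective = Inf, status = "diverged"))
  }
}
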