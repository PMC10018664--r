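#' Save a trained predictor as a reloadable bundle
#'
#' Writes `<stem>.rds` (the full predictor object, R-native) and a plain-text
#' sidecar manifest `<stem>_manifest.json` describing the architecture,
#' training configuration, parameter count and (optionally) the normalizer
#' the predictor was trained under.
#'
#' @param trained A `trained_predictor`.
#' @param stem File-path stem (without extension).
#' @param norm Optional [normalizer()] stored in the manifest so evaluation
#'   can denormalize to mm.
#' @return The stem, invisibly.
#' @export
save_predictor <- function(trained, stem, norm = NULL) {
  if (!inherits(trained, "trained_predictor")) stopf("`trained` must be a trained_predictor")
  saveRDS(trained, paste0(stem, ".rds"))
  manifest <- list(
    class = "trained_predictor",
    architecture = trained$spec$architecture,
    n_layers = trained$spec$n_layers,
    units_per_layer = trained$spec$units_per_layer,
    hidden_activation = trained$spec$hidden_activation,
    output_activation = trained$spec$output_activation,
    multistep = trained$spec$multistep,
    window = unclass(trained$spec$window),
    train_config = unclass(trained$config),
    n_parameters = n_parameters(trained),
    status = trained$status,
    normalizer = if (!is.null(norm)) list(y_min = norm$y_min, y_max = norm$y_max)
  )
  jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(stem)
}

#' Reload a predictor bundle written by [save_predictor()]
#'
#' @param stem The stem passed to [save_predictor()].
#' @return List with `predictor` and `norm` (a [normalizer()] or NULL).
#' @export
load_predictor <- function(stem) {
  rds <- paste0(stem, ".rds")
  if (!file.exists(rds)) stopf("no predictor bundle at '%s'", rds)
  trained <- readRDS(rds)
  norm <- NULL
  mf <- paste0(stem, "_manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf)
    if (!is.null(manifest$normalizer))
      norm <- normalizer(manifest$normalizer$y_min, manifest$normalizer$y_max)
  }
  list(predictor = trained, norm = norm)
}
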