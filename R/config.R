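# Run configuration (YAML), manifests, and report plumbing shared by the
# analysis drivers.

#' Default run configuration
#'
#' @param seed Integer RNG seed for the run.
#' @param rates A `wb_rates`.
#' @param control A `wb_control`.
#' @param outdir Output directory for artifacts.
#' @param ... Protocol-specific parameters stored verbatim.
#' @return A list of class `wb_config`, fully serializable to YAML.
#' @export
wb_config <- function(seed = 1L, rates = action_rates(), control = wb_control(),
                      outdir = "results", ...) {
  structure(
    list(seed = as.integer(seed),
         rates = unclass(rates),
         control = unclass(control),
         outdir = outdir,
         params = list(...)),
    class = "wb_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized top-level sections: `seed`, `rates` (fields of
#' [action_rates()]), `control` (fields of [wb_control()]), `outdir`,
#' `params` (free-form protocol parameters) and `registry` (passed to
#' [registry_from_config()], extending the default registry).
#'
#' @param path YAML file path.
#' @return A list with elements `config` (`wb_config`) and `registry`
#'   (`wb_registry`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rates <- do.call(action_rates, raw$rates %||% list())
  control <- do.call(wb_control, raw$control %||% list())
  cfg <- wb_config(seed = raw$seed %||% 1L, rates = rates, control = control,
                   outdir = raw$outdir %||% "results")
  cfg$params <- raw$params %||% list()
  registry <- if (is.null(raw$registry)) default_registry()
              else registry_from_config(raw$registry, base = default_registry())
  list(config = cfg, registry = registry)
}

#' Write a run configuration to YAML
#'
#' @param config A `wb_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every run directory carries a manifest embedding the configuration
#' verbatim plus the seed and package version, so any artifact can be
#' regenerated bit-identically.
#'
#' @param config A `wb_config`.
#' @param dir Output directory (created if needed).
#' @param extra Named list of extra fields recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, dir, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- c(list(
    package = "wormbench",
    version = as.character(utils::packageVersion("wormbench")),
    seed = config$seed,
    config = unclass(config)
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
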