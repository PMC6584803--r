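# shared internal helpers

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

centroid <- function(coords) colMeans(coords)

#' Read a run configuration file
#'
#' YAML holding the pipeline's tunable settings: `contact_threshold` (A),
#' `epitope_cutoff` (%), `inhibition_cutoff` (%), `atom_mode`, `window` (ns),
#' `stride` (ns), `seed`, optional `aliases` (isoform name map) and file
#' paths. Missing keys take the package defaults. The config round-trips to
#' file losslessly via [yaml::write_yaml()].
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return named list of settings with class `cx_run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(contact_threshold = 2.0, epitope_cutoff = 55,
                   inhibition_cutoff = 50, atom_mode = "all",
                   window = NULL, stride = 0.01, seed = 1L, aliases = NULL)
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg)
  if (out$contact_threshold <= 0) stop("contact_threshold must be positive")
  if (out$epitope_cutoff < 0 || out$epitope_cutoff > 100) stop("epitope_cutoff outside [0, 100]")
  if (out$inhibition_cutoff < 0 || out$inhibition_cutoff > 100) stop("inhibition_cutoff outside [0, 100]")
  structure(out, class = "cx_run_config")
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the configuration (and its digest), seeds, package version and
#' timestamp in a plain-text YAML manifest next to the run's outputs, so any
#' result file can be traced to the exact settings that produced it.
#'
#' @param config a `cx_run_config` (or plain list of settings).
#' @param path output manifest path (YAML).
#' @param outputs optional character vector of files the run wrote.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(config, path, outputs = character()) {
  cfg <- unclass(config)
  digest <- substr(tools::md5sum(
    {tf <- tempfile(); yaml::write_yaml(cfg, tf); tf}), 1, 12)
  manifest <- list(
    package = "connexitope",
    version = as.character(utils::packageVersion("connexitope")),
    config = cfg,
    config_hash = unname(digest),
    outputs = outputs,
    written = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
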