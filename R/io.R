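# Configuration files, tabular results and run management.
#
# All tables go through data.table's fwrite/fread, whose shortest
# round-trip number formatting makes CSV output lossless for doubles.
# Run manifests capture everything needed to re-execute a run
# bit-identically: the full configuration, the root seed and the package
# version, plus an inventory of the files written.

#' Load an experiment configuration from YAML
#'
#' Reads a flat YAML file of `experiment_config` keys, fills unset keys
#' with the defaults, validates, and rejects unknown keys by name.  An
#' empty file yields the default configuration.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$sigma_db)) vals$sigma_db <- unlist(vals$sigma_db)
  do.call(experiment_config, vals)
}

#' Write an experiment configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))` restores
#' `cfg` exactly.
#'
#' @param cfg an `experiment_config`.
#' @param path output YAML path.
#' @export
dump_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$sigma_db <- as.list(out$sigma_db)   # keep channel names in the YAML map
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a results table to CSV
#'
#' Lossless full-precision CSV writer for the package's tabular outputs.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param schema optional character vector of required column names; a
#'   mismatch is a format error.
#' @export
write_results <- function(table, path, schema = NULL) {
  if (!is.data.frame(table)) stopf("`table` must be a data.frame")
  if (!is.null(schema) && !all(schema %in% names(table))) {
    stopf("table lacks required column(s): %s",
          paste(setdiff(schema, names(table)), collapse = ", "))
  }
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    # 17 significant digits guarantee an exact double round-trip
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read a results table from CSV
#'
#' @param path CSV path written by [write_results()].
#' @param schema optional character vector of required column names.
#' @return a data.frame.
#' @export
read_results <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("results file not found: %s", path)
  out <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!is.null(schema) && !all(schema %in% names(out))) {
    stopf("file %s lacks required column(s): %s", path,
          paste(setdiff(schema, names(out)), collapse = ", "))
  }
  out
}

#' Derive reproducible seed streams
#'
#' Deterministically expands a root seed into `n` independent stream seeds
#' so that individual experiment components can be re-run in isolation.
#'
#' @param root_seed integer root seed.
#' @param n number of stream seeds.
#' @return an integer vector of length `n`, each below 2^31.
#' @export
derive_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(root_seed)
  sample.int(.Machine$integer.max, n)
}

#' Write a run manifest
#'
#' Records, next to a run's output files, everything needed to re-execute
#' it bit-identically: the full configuration, root seed, package version
#' and an inventory of the written files with their row counts.
#'
#' @param dir output directory of the run.
#' @param cfg the `experiment_config` used.
#' @param files character vector of CSV files written (paths relative to
#'   `dir` or absolute).
#' @param name manifest file name.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, cfg, files = character(), name = "manifest.yaml") {
  inventory <- lapply(files, function(f) {
    p <- if (file.exists(f)) f else file.path(dir, f)
    list(file = basename(p),
         rows = if (file.exists(p)) nrow(data.table::fread(p)) else NA_integer_)
  })
  manifest <- list(
    package = "glintloc",
    version = as.character(utils::packageVersion("glintloc")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    root_seed = cfg$seed,
    config = unclass(cfg),
    outputs = inventory
  )
  path <- file.path(dir, name)
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Plot an entropy map
#'
#' Filled-point Lambert-projection map of per-direction entropy, one panel
#' per flutter rate.  Requires ggplot2.
#'
#' @param maps the `maps` table from [run_entropy_maps()].
#' @return a ggplot object.
#' @export
plot_entropy_map <- function(maps) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_entropy_map requires the ggplot2 package")
  }
  ggplot2::ggplot(maps, ggplot2::aes(x = x, y = y, colour = entropy_bits)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~flutter_hz, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_viridis_c(name = "entropy (bits)",
                                    direction = -1) +
    ggplot2::labs(x = "Lambert x (right)", y = "Lambert y (up)") +
    ggplot2::theme_minimal()
}
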