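#' Write a run manifest
#'
#' Records the provenance of a command-line run: hash of the configuration
#' file, seed, package version, timestamp and an MD5 hash per output file.
#' Two runs with the same configuration and seed produce identical output
#' hashes, which is how determinism of the CLI is audited.
#'
#' @param path Manifest destination (JSON).
#' @param config_file Configuration file the run used (hashed), or `NULL`.
#' @param seed Integer seed of the run.
#' @param outputs Character vector of output file paths (hashed).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config_file = NULL, seed = NA_integer_,
                           outputs = character()) {
  hash <- function(f) unname(tools::md5sum(f))
  manifest <- list(
    package = "rootbox",
    version = as.character(utils::packageVersion("rootbox")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (is.null(config_file)) NULL else
      list(file = basename(config_file), md5 = hash(config_file)),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = hash(f)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
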