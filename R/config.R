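#' Read and write run configurations
#'
#' A run configuration is a structured YAML file mirroring the
#' [analysis_config], [feature_config] and [synthetic_spec] field names, plus
#' paths and a seed, so that any run can be replayed exactly from its
#' archived configuration. Unknown fields are rejected so that typos fail
#' loudly, and every offending field is named.
#'
#' @param path YAML file path.
#' @return A named list with elements `analysis` ([analysis_config]),
#'   `features` ([feature_config]), `synthetic` ([synthetic_spec]) — each
#'   present only if the corresponding block exists — plus any scalar fields
#'   (`seed`, `model`, `out`, `images`, `labels`, `pixel_size_um`, ...).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  out <- raw
  build <- function(block, ctor, name) {
    if (is.null(block)) return(NULL)
    known <- names(formals(ctor))
    bad <- setdiff(names(block), known)
    if (length(bad)) {
      abort(sprintf("unknown %s field(s): %s", name,
                    paste(bad, collapse = ", ")))
    }
    do.call(ctor, block)
  }
  out$analysis <- build(raw$analysis, analysis_config, "analysis")
  out$features <- build(raw$features, feature_config, "features")
  out$synthetic <- build(raw$synthetic, synthetic_spec, "synthetic")
  out
}

#' @rdname read_run_config
#' @param config A list as returned by [read_run_config] (classed blocks are
#'   flattened back to plain lists).
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}
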