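#' Read a run configuration from YAML or JSON
#'
#' File type is decided by extension (`.yaml` / `.yml` / `.json`). Parse
#' errors from malformed files are propagated with the parser's
#' line/column diagnostics.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(path))
  if (ext == "json") return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  stop("unsupported config format: .", ext, " (use YAML or JSON)",
       call. = FALSE)
}

#' Write the resolved configuration sidecar
#'
#' Every CLI output directory carries a sidecar recording the fully
#' resolved configuration, seed and package version, so a run can be
#' reproduced exactly from its outputs.
#'
#' @param config named list (already resolved).
#' @param path output path (`.yaml` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_config_sidecar <- function(config, path) {
  config$evorescue_version <-
    as.character(utils::packageVersion("evorescue"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else {
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"), path)
  }
  invisible(path)
}

# expands a grid specification (named lists of values) into a data frame;
# an explicit list of rows is also accepted
grid_from_config <- function(spec) {
  if (is.data.frame(spec)) return(spec)
  stopifnot(is.list(spec), length(spec) > 0)
  if (!is.null(names(spec)) && all(nzchar(names(spec)))) {
    return(expand.grid(spec, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(spec, function(r) as.data.frame(r)))
}
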