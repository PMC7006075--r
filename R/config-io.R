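#' Read method configuration from a YAML or key=value file
#'
#' The file may contain top-level sections `nrlmf:` and `ensemble:` (YAML)
#' or flat `section.key = value` lines; unknown keys are rejected. Missing
#' fields keep the package defaults.
#'
#' @param path configuration file.
#' @return List with elements `nrlmf` (an [nrlmf_config()]) and `ensemble`
#'   (an [ensemble_config()]).
#' @export
read_bictr_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.null(raw) || !is.list(raw)) raw <- read_flat_config(path)
  known <- c("nrlmf", "ensemble")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown config sections: ", paste(extra, collapse = ", "))
  }
  nrlmf_args <- as.list(raw$nrlmf %||% list())
  ens_args <- as.list(raw$ensemble %||% list())
  check_config_keys(nrlmf_args, names(formals(nrlmf_config)), "nrlmf")
  check_config_keys(ens_args, names(formals(ensemble_config)), "ensemble")
  list(nrlmf = do.call(nrlmf_config, nrlmf_args),
       ensemble = do.call(ensemble_config, ens_args))
}

check_config_keys <- function(args, allowed, section) {
  extra <- setdiff(names(args), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown %s config keys: %s", section,
                 paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

# "section.key = value" lines; '#' starts a comment.
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("config keys must be section.key: ", key)
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else if (val %in% c("true", "false"))
      val == "true" else val
    out[[parts[1]]][[parts[2]]] <- parsed
  }
  out
}
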