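run_config_defaults <- function() {
  list(lambda = 3, omega = 0.7, C = 8192, gamma = 8.0,
       ensemble_k = 4, seed = 1, property_table_path = NA_character_)
}

#' Build a run configuration
#'
#' Flat key-value configuration shared by all pipeline commands. Values are
#' resolved with precedence overrides > config file > defaults. The config
#' file is plain text, one `key = value` per line, `#` comments allowed.
#' Defaults are the package's operating point: `lambda = 3`, `omega = 0.7`,
#' `C = 8192`, `gamma = 8`, `ensemble_k = 4`.
#'
#' @param path Optional path to a config file.
#' @param overrides Named list of values taking precedence over the file.
#' @return An object of class `run_config` (a validated named list with a
#'   stable `hash` field recorded in every output artifact).
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path) && !is.na(path)) {
    if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
    for (line in readLines(path)) {
      line <- sub("#.*", "", line)
      if (!grepl("=", line, fixed = TRUE)) next
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(cfg)) {
        abort_config(paste0("unknown config key: ", key))
      }
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (is.na(num)) val else num
    }
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) abort_config(paste0("unknown config key: ", bad[1]))
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
  cfg$hash <- rlang::hash(cfg[sort(names(cfg))])
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$lambda < 0 || cfg$lambda != round(cfg$lambda)) {
    abort_config("`lambda` must be a nonnegative integer.")
  }
  if (cfg$omega <= 0 || cfg$omega > 1) abort_config("`omega` must lie in (0, 1].")
  if (cfg$C <= 0) abort_config("`C` must be positive.")
  if (cfg$gamma <= 0) abort_config("`gamma` must be positive.")
  if (cfg$ensemble_k < 2) abort_config("`ensemble_k` must be >= 2.")
  invisible(cfg)
}

config_properties <- function(cfg) {
  if (is.na(cfg$property_table_path)) default_properties()
  else read_property_table(cfg$property_table_path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in setdiff(names(x), "hash")) cat("  ", k, " = ", x[[k]], "\n", sep = "")
  cat("  hash = ", x$hash, "\n", sep = "")
  invisible(x)
}
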