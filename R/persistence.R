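MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained model as JSON
#'
#' Persists everything [predict.pseaac_svm()] and [discriminant_weights()]
#' need — kernel parameters, support vectors, oriented dual coefficients,
#' Platt calibration and the training feature matrix — as a versioned,
#' plain-text JSON archive. A restored model predicts identically to the
#' original because prediction is computed directly from these fields.
#'
#' @param model A `pseaac_svm`.
#' @param path Output path (`.json`).
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a `pseaac_svm`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pseaac_svm"))
  out <- list(
    format_version = MODEL_FORMAT_VERSION,
    kernel = model$kernel, C = model$C, gamma = model$gamma,
    rho = model$rho, coefs = model$coefs, index = model$index,
    platt = as.list(model$platt),
    feature_names = model$feature_names,
    x = unname(model$x),
    y = model$y,
    meta = model$meta
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort_input(paste0("model file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$format_version) || raw$format_version > MODEL_FORMAT_VERSION) {
    abort_input("unsupported model format version.")
  }
  x <- if (is.list(raw$x)) do.call(rbind, raw$x) else raw$x
  colnames(x) <- raw$feature_names
  structure(
    list(x = x, y = as.integer(raw$y), C = raw$C, gamma = raw$gamma,
         kernel = raw$kernel, sv = x[raw$index, , drop = FALSE],
         coefs = raw$coefs, rho = raw$rho, index = raw$index,
         platt = c(a = raw$platt$a, b = raw$platt$b),
         feature_names = raw$feature_names,
         meta = as.list(raw$meta)),
    class = "pseaac_svm"
  )
}

#' Save / load an ensemble as a manifest plus member archives
#'
#' Writes `member_<i>.json` model archives and a `manifest.json` recording
#' the partition seed and the negative-id assignments.
#'
#' @param model A `pseaac_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `write_ensemble()` returns `dir` invisibly; `read_ensemble()`
#'   returns a `pseaac_ensemble`.
#' @export
write_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "pseaac_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("member_%d.json", seq_along(model$members))
  purrr::walk2(model$members, files,
               function(m, f) write_model(m, file.path(dir, f)))
  manifest <- list(format_version = MODEL_FORMAT_VERSION,
                   members = files,
                   partition_seed = model$partition_seed,
                   subset_assignments = as.list(model$subset_assignments))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) abort_input(paste0("ensemble manifest not found: ", mf_path))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  members <- purrr::map(mf$members, function(f) read_model(file.path(dir, f)))
  assignments <- unlist(mf$subset_assignments)
  structure(list(members = members,
                 partition_seed = mf$partition_seed %||% NA_integer_,
                 subset_assignments = assignments),
            class = "pseaac_ensemble")
}
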