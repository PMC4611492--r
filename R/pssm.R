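#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard two-block ASCII matrix that PSI-BLAST writes with
#' `-out_ascii_pssm`: per position, 20 integer log-odds columns followed by
#' 20 weighted-observed-percentage columns. Only the percentage block is
#' used: it is divided by 100 and each row renormalized to sum to 1. A row
#' whose percentages are all zero (PSI-BLAST emits these where a position
#' has no alignment evidence) becomes a one-hot row on the query residue.
#' Columns are reordered from the file's header ordering to the canonical
#' alphabetical ordering.
#'
#' @param path Path to a PSI-BLAST ASCII PSSM file.
#' @param seq_id Identifier for the profile; defaults to the file name
#'   without extension.
#' @return A `frequency_profile` with `source = "parsed_pssm"`. The query
#'   sequence read from the residue column is attached as attribute
#'   `"query"`.
#' @export
read_psiblast_pssm <- function(path, seq_id = NULL) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  seq_id <- seq_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)

  # header: the line listing 40 single-letter residue codes
  toks <- strsplit(trimws(lines), "\\s+")
  is_header <- vapply(toks, function(t) {
    length(t) == 40 && all(t %in% AA_ALPHABET)
  }, logical(1))
  if (!any(is_header)) {
    abort_input(paste0("malformed PSSM header in ", path,
                       ": no line with 40 residue-code columns found."))
  }
  h <- which(is_header)[1]
  file_order <- toks[[h]][1:20]

  rows <- list(); residues <- character(0)
  for (i in seq((h + 1), length(lines))) {
    t <- toks[[i]]
    if (length(t) == 0 || is.na(suppressWarnings(as.integer(t[1])))) break
    if (length(t) < 42) {
      abort_input(paste0("PSSM line ", i, ": expected >= 42 fields, got ",
                         length(t), "."))
    }
    pos <- as.integer(t[1])
    if (pos != length(rows) + 1) {
      abort_input(paste0("PSSM line ", i, ": position index ", pos,
                         " out of order."))
    }
    perc <- suppressWarnings(as.numeric(t[23:42]))
    if (any(is.na(perc))) {
      abort_input(paste0("PSSM line ", i, ": non-numeric percentage cell."))
    }
    residues <- c(residues, toupper(t[2]))
    rows[[pos]] <- perc
  }
  if (length(rows) == 0) abort_input(paste0("no matrix rows found in ", path))

  mat <- do.call(rbind, rows)
  colnames(mat) <- file_order
  mat <- mat[, AA_ALPHABET, drop = FALSE]

  zero <- rowSums(mat) == 0
  if (any(zero)) {
    idx <- aa_index(residues[zero])
    if (any(is.na(idx))) {
      abort_input(paste0("all-zero PSSM row at position ", which(zero)[is.na(idx)][1],
                         " with non-standard query residue; cannot impute."))
    }
    mat[which(zero), ] <- 0
    mat[cbind(which(zero), idx)] <- 100
  }
  mat <- mat / rowSums(mat)
  out <- frequency_profile(mat, seq_id = seq_id, source = "parsed_pssm")
  attr(out, "query") <- paste(residues, collapse = "")
  out
}
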