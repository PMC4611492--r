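#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of sequences. Residues are uppercased;
#' any character that is not one of the 20 standard amino-acid letters or the
#' ambiguity symbol `X` is replaced by `X` with a warning (gap characters in
#' plain sequence files included). Use [read_alignment()] for aligned FASTA
#' where gaps must be preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header) and
#'   `residues`, one row per record in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "wyhk"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  recs <- read_fasta_raw(path)
  cleaned <- clean_residues(recs$residues, recs$id, allow_gaps = FALSE)
  tibble(id = recs$id, residues = cleaned)
}

#' Read an aligned FASTA file
#'
#' As [read_fasta()] but gap characters (`-`, `.`) are preserved (as `-`) so
#' the result can feed [observed_profile()]. All rows must have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `residues`.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta_raw(path)
  cleaned <- clean_residues(recs$residues, recs$id, allow_gaps = TRUE)
  if (length(unique(nchar(cleaned))) > 1) {
    abort_input("alignment rows have unequal lengths.")
  }
  tibble(id = recs$id, residues = cleaned)
}

# Biostrings does the FASTA-format heavy lifting; we impose the package's
# record-level rules on top.
read_fasta_raw <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_input(paste0("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  )
  if (length(set) == 0) abort_input(paste0("FASTA file contains no records: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    abort_input(paste0("record with empty sequence: ", ids[empty[1]]))
  }
  list(id = unname(ids), residues = unname(seqs))
}

clean_residues <- function(seqs, ids, allow_gaps = FALSE) {
  ok <- c(AA_ALPHABET, AA_AMBIGUOUS)
  if (allow_gaps) {
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
    ok <- c(ok, "-")
  }
  pattern <- paste0("[^", paste(ok, collapse = ""), "]")
  bad <- grepl(pattern, seqs)
  if (any(bad)) {
    warn(paste0("non-standard residues mapped to '", AA_AMBIGUOUS, "' in: ",
                paste(ids[bad], collapse = ", ")))
    seqs[bad] <- gsub(pattern, AA_AMBIGUOUS, seqs[bad])
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `residues` (as returned by
#'   [read_fasta()]); extra columns are ignored.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  lines <- unlist(purrr::map2(seqs$id, seqs$residues, function(id, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}
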