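#' Construct a frequency profile
#'
#' A frequency profile is an `L x 20` row-stochastic matrix giving, for each
#' sequence position, a probability distribution over the 20 standard amino
#' acids (columns in canonical order, see [aa_alphabet()]). Profiles come
#' from three sources: observed alignment-column frequencies
#' ([observed_profile()]), pseudo-count-corrected target frequencies
#' ([apply_pseudocounts()]), or parsed PSI-BLAST output
#' ([read_psiblast_pssm()]).
#'
#' @param matrix Numeric `L x 20` matrix; rows must sum to 1 within 1e-9 and
#'   entries lie in `[0, 1]`.
#' @param seq_id Sequence identifier.
#' @param source One of `"observed"`, `"pseudo_counted"`, `"parsed_pssm"`.
#' @return An object of class `frequency_profile`.
#' @export
frequency_profile <- function(matrix, seq_id = "seq",
                              source = c("observed", "pseudo_counted", "parsed_pssm")) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1 || ncol(matrix) != 20) {
    abort_input("profile matrix must have >= 1 rows and exactly 20 columns.")
  }
  if (any(!is.finite(matrix)) || any(matrix < -1e-12) || any(matrix > 1 + 1e-12)) {
    abort_input("profile entries must be probabilities in [0, 1].")
  }
  rs <- rowSums(matrix)
  if (max(abs(rs - 1)) > 1e-9) {
    abort_input(paste0("profile rows must sum to 1 (worst deviation ",
                       format(max(abs(rs - 1))), ")."))
  }
  colnames(matrix) <- AA_ALPHABET
  rownames(matrix) <- NULL
  structure(list(seq_id = seq_id, matrix = matrix, source = source),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("<frequency_profile> ", x$seq_id, ": L = ", nrow(x$matrix),
      ", source = ", x$source, "\n", sep = "")
  invisible(x)
}

#' @rdname frequency_profile
#' @param x A `frequency_profile`.
#' @param ... Unused.
#' @export
tidy.frequency_profile <- function(x, ...) {
  as_tibble(x$matrix) |>
    dplyr::mutate(seq_id = x$seq_id, position = dplyr::row_number(),
                  .before = 1) |>
    tidyr::pivot_longer(dplyr::all_of(AA_ALPHABET),
                        names_to = "residue", values_to = "freq")
}

#' Observed column frequencies of a multiple alignment
#'
#' Counts, for every alignment column, the standard residues observed and
#' converts them to relative frequencies `f_ij` = (count of residue i in
#' column j) / (standard residues in column j). Gap and ambiguity characters
#' are excluded from both numerator and denominator; a column with no
#' standard residue at all is an error.
#'
#' @param msa A tibble with a `residues` column (see [read_alignment()]) or a
#'   character vector of equal-length aligned sequences.
#' @param seq_id Identifier for the resulting profile; defaults to the first
#'   sequence's id when available.
#' @return A `frequency_profile` with `source = "observed"`.
#' @export
#' @examples
#' observed_profile(c("AR", "AR", "R-"))$matrix
observed_profile <- function(msa, seq_id = NULL) {
  if (is.data.frame(msa)) {
    seq_id <- seq_id %||% msa$id[1] %||% "msa"
    msa <- msa$residues
  }
  seq_id <- seq_id %||% "msa"
  if (length(msa) < 1) abort_input("alignment must contain at least one sequence.")
  lens <- nchar(msa)
  if (length(unique(lens)) > 1) abort_input("alignment rows have unequal lengths.")
  L <- lens[1]
  if (L < 1) abort_input("alignment has zero columns.")
  chars <- matrix(unlist(strsplit(toupper(msa), "", fixed = TRUE)),
                  nrow = length(msa), byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(aa_index(chars[, j]), nbins = 20)
  }, numeric(20))
  tot <- colSums(counts)
  if (any(tot == 0)) {
    abort_input(paste0("alignment column with no standard residue: column ",
                       which(tot == 0)[1]))
  }
  frequency_profile(t(counts) / tot, seq_id = seq_id, source = "observed")
}

#' Blend observed frequencies with substitution-model pseudo-counts
#'
#' Converts observed alignment-column frequencies into target frequencies by
#' blending each column with its substitution-implied expectation. For
#' column `j` let `alpha_j` be the number of distinct standard residues
#' observed minus one, and let the pseudo-count for residue `i` be
#' `g_ij = sum_k (f_kj / p_k) q_ik`, with `p` the background and `q` the
#' joint pair frequencies of `model`. The target frequency is
#' `m_ij = (alpha_j f_ij + beta g_ij) / (alpha_j + beta)`. Because the row
#' marginals of `q` equal `p`, every column of pseudo-counts sums to 1 and
#' the result is again row-stochastic. A perfectly conserved column
#' (`alpha_j = 0`) is replaced entirely by its pseudo-counts; as
#' `beta -> 0` the observed frequencies are recovered.
#'
#' @param f A `frequency_profile` with `source = "observed"`.
#' @param model A [substitution_model()]; default BLOSUM62 with `beta = 10`.
#' @return A `frequency_profile` with `source = "pseudo_counted"`.
#' @export
apply_pseudocounts <- function(f, model = substitution_model()) {
  stopifnot(inherits(f, "frequency_profile"))
  if (!inherits(model, "substitution_model")) {
    abort_input("`model` must be a substitution_model.")
  }
  if (f$source != "observed") {
    abort_input("pseudo-counts apply to profiles with source = 'observed'.")
  }
  F <- f$matrix
  p <- model$background
  q <- model$joint_freqs
  beta <- model$beta
  alpha <- rowSums(F > 0) - 1
  # g[l, i] = sum_k F[l, k] / p[k] * q[i, k]
  G <- sweep(F, 2, p, "/") %*% t(q)
  M <- (alpha * F + beta * G) / (alpha + beta)
  M <- M / rowSums(M)
  frequency_profile(M, seq_id = f$seq_id, source = "pseudo_counted")
}

#' Profile-consensus sequence
#'
#' Collapses a frequency profile to the consensus string built from the most
#' frequent amino acid in every column; this consensus carries the
#' evolutionary information of the profile into downstream PseAAC
#' featurization. Ties are broken deterministically toward the earlier
#' residue in the canonical ordering.
#'
#' @param m A `frequency_profile`.
#' @return An object of class `profile_sequence` with fields `seq_id`,
#'   `residues` (length-L string over the 20 standard letters) and
#'   `top_freqs` (the winning frequency per position).
#' @export
#' @examples
#' pr <- observed_profile(c("ACD", "ACD"))
#' consensus_sequence(pr)$residues
consensus_sequence <- function(m) {
  stopifnot(inherits(m, "frequency_profile"))
  idx <- max.col(m$matrix, ties.method = "first")
  structure(
    list(seq_id = m$seq_id,
         residues = paste(AA_ALPHABET[idx], collapse = ""),
         top_freqs = m$matrix[cbind(seq_along(idx), idx)]),
    class = "profile_sequence"
  )
}

#' @export
print.profile_sequence <- function(x, ...) {
  cat("<profile_sequence> ", x$seq_id, ": L = ", nchar(x$residues), "\n", sep = "")
  invisible(x)
}

#' @rdname consensus_sequence
#' @param x A `profile_sequence`.
#' @param ... Unused.
#' @export
tidy.profile_sequence <- function(x, ...) {
  tibble(seq_id = x$seq_id, position = seq_len(nchar(x$residues)),
         residue = aa_chars(x$residues), top_freq = x$top_freqs)
}

#' Write / read a frequency profile as TSV
#'
#' Plain-text interchange: one header line naming the canonical column
#' order, then L rows of probabilities.
#'
#' @param profile A `frequency_profile`.
#' @param path File path.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a `frequency_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "frequency_profile"))
  df <- as.data.frame(profile$matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seq_id=", profile$seq_id, " source=", profile$source), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header, regexec("# seq_id=(\\S+) source=(\\S+)", header))[[1]]
  if (length(meta) != 3) abort_input(paste0("malformed profile TSV header: ", path))
  df <- read.delim(path, skip = 1, check.names = FALSE)
  if (!identical(names(df), AA_ALPHABET)) {
    abort_input("profile TSV columns must be the canonical amino-acid ordering.")
  }
  frequency_profile(as.matrix(df), seq_id = meta[2], source = meta[3])
}
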