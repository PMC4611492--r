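onehot_profile <- function(residues, seq_id = "seq", source = "observed") {
  aa <- aa_alphabet()
  chars <- strsplit(residues, "")[[1]]
  m <- matrix(0, length(chars), 20)
  m[cbind(seq_along(chars), match(chars, aa))] <- 1
  frequency_profile(m, seq_id = seq_id, source = source)
}

random_stochastic_profile <- function(L, seq_id = "seq", source = "observed") {
  g <- matrix(rgamma(L * 20, shape = 0.5), L, 20)
  frequency_profile(g / rowSums(g), seq_id = seq_id, source = source)
}

tmp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# PSI-BLAST-style ASCII PSSM fixture. `perc` is an L x 20 matrix in the
# file's own (BLAST header) column order; log-odds block is filled with
# zeros, which the parser must ignore.
blast_col_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

write_pssm_fixture <- function(path, residues, perc) {
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("            ",
                     paste(sprintf("%3s", blast_col_order), collapse = ""),
                     paste(sprintf("%4s", blast_col_order), collapse = "")))
  chars <- strsplit(residues, "")[[1]]
  rows <- vapply(seq_len(nrow(perc)), function(i) {
    paste0(sprintf("%5d %s  ", i, chars[i]),
           paste(rep(" 0", 20), collapse = ""), " ",
           paste(sprintf("%4g", perc[i, ]), collapse = ""),
           "  0.00      0.00")
  }, character(1))
  writeLines(c(header, rows, ""), path)
  path
}

# tiny separable 2-class feature tibble
separable_features <- function(n_per_class = 4, gap = 4) {
  tibble::tibble(
    seq_id = paste0("s", seq_len(2 * n_per_class)),
    f1 = c(rnorm(n_per_class, gap, 0.1), rnorm(n_per_class, -gap, 0.1)),
    f2 = rnorm(2 * n_per_class, 0, 0.1)
  )
}

separable_labels <- function(n_per_class = 4) {
  rep(c(1L, -1L), each = n_per_class)
}
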