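# Canonical residue ordering used by every matrix and feature vector in the
# package: alphabetical single-letter codes. Stated once, used everywhere.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity symbol: any non-standard input character maps here on parsing.
AA_AMBIGUOUS <- "X"

# Characters tolerated in alignments but excluded from all 20-dimensional math.
AA_GAP_CHARS <- c("-", ".")

#' Canonical amino-acid ordering
#'
#' The 20 standard amino acids in the fixed column order used by every
#' profile matrix, property table and feature vector in the package
#' (alphabetical single-letter codes). Ties in profile columns are broken
#' toward the earlier residue in this ordering.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ALPHABET

# Split a residue string into single characters.
aa_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map residue characters to canonical indices; non-standard -> NA.
aa_index <- function(chars) match(chars, AA_ALPHABET)
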