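# Default seven-property set (canonical residue order). Raw values from
# standard physicochemical compilations: Tanford-type hydrophobicity,
# Hopp-Woods hydrophilicity, side-chain mass (Da), pK1 (alpha-COOH),
# pK2 (alpha-NH3+), isoelectric point pI, and mean accessible surface area
# (A^2, Miller standard state). Fully user-overridable via
# read_property_table(); z-scoring makes all downstream features invariant
# to affine rescaling of any row.
default_property_raw <- local({
  m <- rbind(
    hydrophobicity = c(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38, -1.50, 1.06,
                       0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05, 1.08, 0.81, 0.26),
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                       -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
    side_chain_mass = c(15, 47, 59, 73, 91, 1, 82, 57, 73, 57,
                        75, 58, 42, 72, 101, 31, 45, 43, 130, 107),
    pK1 = c(2.35, 1.71, 1.88, 2.19, 2.58, 2.34, 1.78, 2.32, 2.20, 2.36,
            2.28, 2.18, 1.99, 2.17, 2.17, 2.21, 2.15, 2.29, 2.38, 2.20),
    pK2 = c(9.87, 10.78, 9.60, 9.67, 9.24, 9.60, 8.97, 9.76, 8.90, 9.60,
            9.21, 9.09, 10.60, 9.13, 9.04, 9.15, 9.12, 9.72, 9.39, 9.11),
    pI = c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
           5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.60, 5.96, 5.89, 5.66),
    asa = c(113, 140, 151, 183, 218, 85, 194, 182, 211, 180,
            204, 158, 143, 189, 241, 122, 146, 160, 259, 229)
  )
  colnames(m) <- AA_ALPHABET
  m
})

#' Normalize a physicochemical property table
#'
#' Standardizes each property row to mean 0 and population standard
#' deviation 1 (dividing by `n`, not `n - 1`) across the 20 standard amino
#' acids. The normalized values feed the residue-pair correlation function
#' [theta_pair()]; z-scoring makes every downstream feature invariant to
#' affine rescaling of a raw property row.
#'
#' @param raw Numeric matrix with one row per property and 20 columns in
#'   canonical residue order (column names, if present, must match
#'   [aa_alphabet()]).
#' @return An object of class `property_table` with fields `names`, `raw`,
#'   `normalized` and a precomputed 20 x 20 residue dissimilarity matrix
#'   `theta`.
#' @export
#' @examples
#' pt <- normalize_properties(default_properties()$raw)
#' rowMeans(pt$normalized)
normalize_properties <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20) abort_input("property table must have 20 columns.")
  if (is.null(rownames(raw))) rownames(raw) <- paste0("prop", seq_len(nrow(raw)))
  if (!is.null(colnames(raw)) && !identical(colnames(raw), AA_ALPHABET)) {
    if (!setequal(colnames(raw), AA_ALPHABET)) {
      abort_input("property table columns must be the 20 standard residues.")
    }
    raw <- raw[, AA_ALPHABET, drop = FALSE]
  }
  colnames(raw) <- AA_ALPHABET
  mu <- rowMeans(raw)
  sd_pop <- sqrt(rowMeans((raw - mu)^2))
  if (any(sd_pop < 1e-12)) {
    abort_input(paste0("constant property row (zero variance): ",
                       rownames(raw)[sd_pop < 1e-12][1]))
  }
  normalized <- (raw - mu) / sd_pop
  # theta[a, b] = mean over properties of (H(a) - H(b))^2
  n_prop <- nrow(normalized)
  theta <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (j in seq_len(n_prop)) {
    theta <- theta + outer(normalized[j, ], normalized[j, ], "-")^2
  }
  theta <- theta / n_prop
  structure(list(names = rownames(raw), raw = raw, normalized = normalized,
                 theta = theta),
            class = "property_table")
}

#' Default physicochemical property table
#'
#' The packaged seven-property set (hydrophobicity, hydrophilicity,
#' side-chain mass, pK1, pK2, pI, accessible surface area), normalized.
#' These are the canonical seven properties used by profile-based PseAAC;
#' substitute your own values with [read_property_table()] if needed.
#'
#' @return A `property_table`.
#' @export
default_properties <- function() {
  if (is.null(property_cache$default)) {
    property_cache$default <- normalize_properties(default_property_raw)
  }
  property_cache$default
}
property_cache <- new.env(parent = emptyenv())

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table> ", length(x$names), " properties: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname normalize_properties
#' @param x A `property_table`.
#' @param ... Unused.
#' @export
tidy.property_table <- function(x, ...) {
  as_tibble(x$normalized) |>
    dplyr::mutate(property = x$names, .before = 1) |>
    tidyr::pivot_longer(dplyr::all_of(AA_ALPHABET),
                        names_to = "residue", values_to = "value")
}

#' Read / write a property table as TSV
#'
#' Interchange format: one row per property, first column the property
#' name, then 20 value columns in canonical residue order (header row of
#' residue letters).
#'
#' @param path File path.
#' @return `read_property_table()` returns a normalized `property_table`;
#'   `write_property_table()` returns `path` invisibly.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) != 21) {
    abort_input("property TSV must have a name column plus 20 residue columns.")
  }
  raw <- as.matrix(df[, -1])
  rownames(raw) <- df[[1]]
  normalize_properties(raw)
}

#' @rdname read_property_table
#' @param props A `property_table`.
#' @export
write_property_table <- function(props, path) {
  stopifnot(inherits(props, "property_table"))
  df <- data.frame(property = props$names, props$raw, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable content hash of the table actually used (recorded in model files).
property_hash <- function(props) rlang::hash(round(props$normalized, 12))
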