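#' Physicochemical dissimilarity of a residue pair
#'
#' The correlation function underlying the sequence-order factors: the mean
#' squared difference of the normalized property values of two residues,
#' `theta(a, b) = (1/J) * sum_j (H_j(a) - H_j(b))^2` over the `J` properties
#' of the table. Symmetric, nonnegative, zero iff the two residues have
#' identical property profiles.
#'
#' @param a,b Standard single-letter residue codes.
#' @param props A [normalize_properties()] table; default packaged set.
#' @return Nonnegative scalar (vectorized over `a`/`b`).
#' @export
#' @examples
#' theta_pair("A", "A")
#' theta_pair("R", "D")
theta_pair <- function(a, b, props = default_properties()) {
  stopifnot(inherits(props, "property_table"))
  ia <- aa_index(a); ib <- aa_index(b)
  if (any(is.na(ia)) || any(is.na(ib))) {
    abort_input("theta_pair() is defined only for the 20 standard residues.")
  }
  unname(props$theta[cbind(ia, ib)])
}

#' Sequence-order correlation factors
#'
#' For a profile-consensus sequence of length `L`, the k-th correlation
#' factor averages the physicochemical dissimilarity of all residue pairs
#' `k` positions apart:
#' `theta_k = (1/(L-k)) * sum_{i=1}^{L-k} theta(p_i, p_{i+k})`, k = 1..lambda.
#'
#' @param p A `profile_sequence` (see [consensus_sequence()]) or a plain
#'   character string over the 20 standard letters.
#' @param lambda Number of factors; must satisfy `lambda < L`.
#' @param props A `property_table`.
#' @return Numeric vector of length `lambda` (length 0 when `lambda = 0`).
#' @export
#' @examples
#' correlation_factors("ARNDARND", lambda = 3)
correlation_factors <- function(p, lambda, props = default_properties()) {
  res <- if (inherits(p, "profile_sequence")) p$residues else p
  stopifnot(is.character(res), length(res) == 1)
  idx <- aa_index(aa_chars(res))
  if (any(is.na(idx))) {
    abort_input("sequence contains non-standard residues; correlation factors are defined on the 20 standard letters.")
  }
  L <- length(idx)
  if (lambda < 0) abort_input("`lambda` must be >= 0.")
  if (lambda >= L) {
    abort_input(paste0("lambda (", lambda, ") must be smaller than the sequence length (",
                       L, "): lower lambda or drop this sequence."))
  }
  if (lambda == 0) return(numeric(0))
  th <- props$theta
  vapply(seq_len(lambda), function(k) {
    i <- seq_len(L - k)
    mean(th[cbind(idx[i], idx[i + k])])
  }, numeric(1))
}

#' Pseudo amino acid composition features
#'
#' Converts a profile-consensus sequence into the `(20 + lambda)`-dimensional
#' PseAAC vector: the first 20 entries are the residue relative frequencies
#' `f_u` of the consensus, the remaining `lambda` entries are the weighted
#' sequence-order correlation factors. With
#' `D = sum_v f_v + omega * sum_k theta_k`,
#' `x_u = f_u / D` for `u <= 20` and `x_u = omega * theta_{u-20} / D`
#' otherwise, so the vector is nonnegative and sums to 1.
#'
#' @inheritParams correlation_factors
#' @param lambda Sequence-order depth (default 3, the value at which the
#'   classifier performs best).
#' @param omega Weight of the sequence-order part, in `(0, 1]` (default 0.7).
#' @return An object of class `pseaac_vector` with fields `seq_id`,
#'   `lambda`, `omega`, `values` (named, length `20 + lambda`), `theta` and
#'   `comp`.
#' @export
#' @examples
#' x <- pseaac_features("ARNDKLMRKY", lambda = 3, omega = 0.7)
#' sum(x$values)
pseaac_features <- function(p, lambda = 3, omega = 0.7,
                            props = default_properties()) {
  if (!is.numeric(omega) || omega <= 0 || omega > 1) {
    abort_input("`omega` must lie in (0, 1].")
  }
  res <- if (inherits(p, "profile_sequence")) p$residues else p
  seq_id <- if (inherits(p, "profile_sequence")) p$seq_id else "seq"
  theta <- correlation_factors(res, lambda, props)
  idx <- aa_index(aa_chars(res))
  comp <- tabulate(idx, nbins = 20) / length(idx)
  names(comp) <- AA_ALPHABET
  D <- sum(comp) + omega * sum(theta)
  values <- c(comp, omega * theta) / D
  names(values) <- feature_names(lambda)
  structure(list(seq_id = seq_id, lambda = lambda, omega = omega,
                 values = values, theta = theta, comp = comp),
            class = "pseaac_vector")
}

feature_names <- function(lambda) {
  c(AA_ALPHABET, if (lambda > 0) paste0("theta", seq_len(lambda)))
}

#' @export
print.pseaac_vector <- function(x, ...) {
  cat("<pseaac_vector> ", x$seq_id, ": dim = ", length(x$values),
      " (lambda = ", x$lambda, ", omega = ", x$omega, ")\n", sep = "")
  invisible(x)
}

#' @rdname pseaac_features
#' @param x A `pseaac_vector`.
#' @param ... Unused.
#' @export
tidy.pseaac_vector <- function(x, ...) {
  tibble(seq_id = x$seq_id, feature = names(x$values), value = unname(x$values))
}

#' Featurize a batch of sequences
#'
#' Applies [pseaac_features()] to every item and binds the results into a
#' feature tibble (one row per sequence, `seq_id` plus `20 + lambda` feature
#' columns, input order preserved). Sequences shorter than `lambda + 1`
#' violate the correlation-factor precondition: by default the batch
#' errors, naming the offending ids; with `permissive = TRUE` they are
#' dropped with a warning and the rest processed.
#'
#' @param items A list of `profile_sequence` objects, a character vector of
#'   sequences, or a tibble with `id`/`residues` columns.
#' @inheritParams pseaac_features
#' @param permissive Drop too-short sequences instead of failing.
#' @return A tibble with columns `seq_id` and the feature columns.
#' @export
featurize_batch <- function(items, lambda = 3, omega = 0.7,
                            props = default_properties(), permissive = FALSE) {
  if (is.data.frame(items)) {
    ids <- items$id %||% paste0("seq", seq_len(nrow(items)))
    seqs <- items$residues
  } else if (is.character(items)) {
    ids <- names(items) %||% paste0("seq", seq_along(items))
    seqs <- unname(items)
  } else {
    ids <- purrr::map_chr(items, "seq_id")
    seqs <- purrr::map_chr(items, "residues")
  }
  empty <- as_tibble(setNames(
    as.list(c(list(character(0)), rep(list(numeric(0)), 20 + lambda))),
    c("seq_id", feature_names(lambda))
  ))
  if (length(seqs) == 0) return(empty)
  short <- nchar(seqs) <= lambda
  if (any(short)) {
    msg <- paste0("sequences shorter than lambda + 1 = ", lambda + 1, ": ",
                  paste(ids[short], collapse = ", "))
    if (!permissive) abort_input(msg)
    warn(paste0(msg, " (dropped)"))
    ids <- ids[!short]; seqs <- seqs[!short]
    if (length(seqs) == 0) return(empty)
  }
  rows <- purrr::map2(ids, seqs, function(id, s) {
    v <- pseaac_features(s, lambda = lambda, omega = omega, props = props)$values
    dplyr::bind_cols(tibble(seq_id = id), as_tibble(as.list(v)))
  })
  dplyr::bind_rows(rows)
}

#' Write a feature tibble as CSV or LIBSVM sparse text
#'
#' @param features Tibble from [featurize_batch()] (`seq_id` + numeric
#'   feature columns).
#' @param path Output path.
#' @param labels Optional vector of class labels in `{-1, +1}` (required
#'   for LIBSVM output, written as the target column).
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path, labels = NULL) {
  df <- as.data.frame(features)
  if (!is.null(labels)) df <- cbind(df[1], label = labels, df[-1])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
write_features_libsvm <- function(features, path, labels = NULL) {
  mat <- as.matrix(features[, setdiff(names(features), "seq_id")])
  labels <- labels %||% rep(0, nrow(mat))
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    nz <- which(mat[i, ] != 0)
    paste(labels[i], paste0(nz, ":", format(mat[i, nz], digits = 12, trim = TRUE),
                            collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Feature tibble -> plain numeric matrix (drops id/label columns).
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  cols <- setdiff(names(features), c("seq_id", "label"))
  m <- as.matrix(features[, cols])
  if ("seq_id" %in% names(features)) rownames(m) <- features$seq_id
  m
}
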