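# BLOSUM62 half-bit log-odds scores (Henikoff & Henikoff 1992), rows/columns
# in the canonical alphabetical ordering.
blosum62_scores_matrix <- local({
  m <- rbind(
    A = c(4, 0, -2, -1, -2, 0, -2, -1, -1, -1, -1, -2, -1, -1, -1, 1, 0, 0, -3, -2),
    C = c(0, 9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2),
    D = c(-2, -3, 6, 2, -3, -1, -1, -3, -1, -4, -3, 1, -1, 0, -2, 0, -1, -3, -4, -3),
    E = c(-1, -4, 2, 5, -3, -2, 0, -3, 1, -3, -2, 0, -1, 2, 0, 0, -1, -2, -3, -2),
    F = c(-2, -2, -3, -3, 6, -3, -1, 0, -3, 0, 0, -3, -4, -3, -3, -2, -2, -1, 1, 3),
    G = c(0, -3, -1, -2, -3, 6, -2, -4, -2, -4, -3, 0, -2, -2, -2, 0, -2, -3, -2, -3),
    H = c(-2, -3, -1, 0, -1, -2, 8, -3, -1, -3, -2, 1, -2, 0, 0, -1, -2, -3, -2, 2),
    I = c(-1, -1, -3, -3, 0, -4, -3, 4, -3, 2, 1, -3, -3, -3, -3, -2, -1, 3, -3, -1),
    K = c(-1, -3, -1, 1, -3, -2, -1, -3, 5, -2, -1, 0, -1, 1, 2, 0, -1, -2, -3, -2),
    L = c(-1, -1, -4, -3, 0, -4, -3, 2, -2, 4, 2, -3, -3, -2, -2, -2, -1, 1, -2, -1),
    M = c(-1, -1, -3, -2, 0, -3, -2, 1, -1, 2, 5, -2, -2, 0, -1, -1, -1, 1, -1, -1),
    N = c(-2, -3, 1, 0, -3, 0, 1, -3, 0, -3, -2, 6, -2, 0, 0, 1, 0, -3, -4, -2),
    P = c(-1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2, 7, -1, -2, -1, -1, -2, -4, -3),
    Q = c(-1, -3, 0, 2, -3, -2, 0, -3, 1, -2, 0, 0, -1, 5, 1, 0, -1, -2, -2, -1),
    R = c(-1, -3, -2, 0, -3, -2, 0, -3, 2, -2, -1, 0, -2, 1, 5, -1, -1, -3, -3, -2),
    S = c(1, -1, 0, 0, -2, 0, -1, -2, 0, -2, -1, 1, -1, 0, -1, 4, 1, -2, -3, -2),
    T = c(0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1, 0, -1, -1, -1, 1, 5, 0, -2, -2),
    V = c(0, -1, -3, -2, -1, -3, -3, 3, -2, 1, 1, -3, -2, -2, -3, -2, 0, 4, -3, -1),
    W = c(-3, -2, -4, -3, 1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11, 2),
    Y = c(-2, -2, -3, -2, 3, -3, 2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1, 2, 7)
  )
  colnames(m) <- rownames(m)
  m
})

# Standard BLOSUM62 background amino-acid frequencies, canonical order,
# renormalized to sum exactly to 1.
blosum62_background_vec <- local({
  p <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  p / sum(p)
})

# Joint target pair frequencies q_ik implied by the half-bit scores
# s = round(2 log2(q / (p_i p_k))): start from p_i p_k 2^(s/2) and apply
# symmetric iterative proportional fitting so that row marginals equal the
# background exactly (which makes pseudo-count columns sum to 1 exactly).
blosum62_joint <- function() {
  p <- blosum62_background_vec
  q <- outer(p, p) * 2^(blosum62_scores_matrix / 2)
  for (i in 1:200) {
    r <- rowSums(q)
    if (max(abs(r - p)) < 1e-14) break
    d <- sqrt(p / r)
    q <- q * outer(d, d)
  }
  q
}

#' Substitution model for profile pseudo-counts
#'
#' Bundles the joint residue pair frequencies `q_ik`, the background
#' frequencies `p_k` and the pseudo-count weight `beta` used when blending
#' observed alignment-column frequencies with substitution-implied
#' expectations (see [apply_pseudocounts()]). The default model is derived
#' from BLOSUM62: pair frequencies are reconstructed from the published
#' half-bit log-odds scores and background frequencies, balanced so that the
#' row marginals of `joint_freqs` equal `background` to machine precision.
#'
#' @param joint_freqs 20 x 20 symmetric matrix of pair frequencies in
#'   canonical residue order (see [aa_alphabet()]). Default: BLOSUM62.
#' @param background Length-20 positive vector of background frequencies
#'   summing to 1. Default: BLOSUM62 background.
#' @param beta Pseudo-count weight (default 10, the PSI-BLAST convention).
#' @return An object of class `substitution_model`.
#' @export
#' @examples
#' m <- substitution_model()
#' all.equal(rowSums(m$joint_freqs), m$background)
substitution_model <- function(joint_freqs = NULL, background = NULL, beta = 10) {
  if (is.null(joint_freqs) && is.null(background)) {
    joint_freqs <- blosum62_joint()
    background <- blosum62_background_vec
  } else if (is.null(joint_freqs) || is.null(background)) {
    abort_input("supply both `joint_freqs` and `background`, or neither.")
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    abort_input("`beta` must be a single positive number.")
  }
  joint_freqs <- as.matrix(joint_freqs)
  background <- as.numeric(background)
  if (!all(dim(joint_freqs) == c(20L, 20L)) || length(background) != 20L) {
    abort_input("`joint_freqs` must be 20 x 20 and `background` length 20.")
  }
  if (any(background <= 0)) abort_input("background frequencies must be positive.")
  if (abs(sum(background) - 1) > 1e-6) {
    abort_input("background frequencies must sum to 1 (within 1e-6).")
  }
  if (max(abs(joint_freqs - t(joint_freqs))) > 1e-9) {
    abort_input("`joint_freqs` must be symmetric.")
  }
  if (max(abs(rowSums(joint_freqs) - background)) > 1e-3) {
    abort_input("row marginals of `joint_freqs` must match `background` within 1e-3.")
  }
  dimnames(joint_freqs) <- list(AA_ALPHABET, AA_ALPHABET)
  names(background) <- AA_ALPHABET
  structure(
    list(joint_freqs = joint_freqs, background = background, beta = beta),
    class = "substitution_model"
  )
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> 20x20 pair frequencies, beta =", x$beta, "\n")
  invisible(x)
}
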