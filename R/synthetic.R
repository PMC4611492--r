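#' Specification for synthetic two-class sequence data
#'
#' Describes a controllable two-class protein dataset for end-to-end
#' testing without PSI-BLAST: positives are enriched in chosen residues
#' (arginine/lysine by default, the residues over-represented in
#' DNA-binding regions), negatives follow the background composition, and
#' per-sequence frequency profiles are produced by smearing the one-hot
#' encoding with Dirichlet noise. All generators are pure functions of the
#' spec (including its seed).
#'
#' @param n_pos,n_neg Class sizes (defaults 30/30).
#' @param length_range Inclusive sequence-length range; minimum 50 by
#'   default, mirroring the usual fragment cutoff for benchmark proteins.
#' @param enrichment Named positive multipliers applied to the background
#'   frequency of selected residues in the positive class (default
#'   `c(R = 2.5, K = 2.5)`).
#' @param order_effect Nonnegative scalar; when positive, consecutive
#'   residues of positive-class sequences are correlated in their
#'   physicochemical properties (next residue reweighted by
#'   `exp(-order_effect * theta(prev, a))`). 0 = i.i.d. sampling.
#' @param profile_noise Dirichlet concentration used to smear one-hot rows
#'   into profiles; larger is closer to one-hot (default 50).
#' @param seed Integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 30, n_neg = 30, length_range = c(50, 200),
                           enrichment = c(R = 2.5, K = 2.5), order_effect = 0,
                           profile_noise = 50, seed = 1) {
  if (n_pos < 1 || n_neg < 1) abort_config("class sizes must be >= 1.")
  if (length(length_range) != 2 || length_range[1] < 2 ||
      length_range[1] > length_range[2]) {
    abort_config("`length_range` must be (min, max) with min >= 2.")
  }
  if (length(enrichment) > 0) {
    if (is.null(names(enrichment)) || !all(names(enrichment) %in% AA_ALPHABET)) {
      abort_config("`enrichment` must be named by standard residues.")
    }
    if (any(enrichment <= 0)) abort_config("enrichment biases must be positive.")
  }
  if (order_effect < 0) abort_config("`order_effect` must be >= 0.")
  if (profile_noise <= 0) abort_config("`profile_noise` (Dirichlet concentration) must be positive.")
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 length_range = as.integer(length_range),
                 enrichment = enrichment, order_effect = order_effect,
                 profile_noise = profile_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Class composition distributions implied by a spec.
spec_compositions <- function(spec) {
  bg <- blosum62_background_vec
  pos <- bg
  if (length(spec$enrichment) > 0) {
    pos[names(spec$enrichment)] <- pos[names(spec$enrichment)] * spec$enrichment
  }
  list(pos = pos / sum(pos), neg = bg)
}

sample_sequence <- function(L, probs, order_effect, theta) {
  if (order_effect == 0) {
    return(paste(sample(AA_ALPHABET, L, replace = TRUE, prob = probs),
                 collapse = ""))
  }
  if (sum(probs > 0) < 2) {
    abort_input("degenerate residue distribution: order correlation needs >= 2 residues with positive mass.")
  }
  idx <- integer(L)
  idx[1] <- sample.int(20, 1, prob = probs)
  for (i in 2:L) {
    w <- probs * exp(-order_effect * theta[idx[i - 1], ])
    idx[i] <- sample.int(20, 1, prob = w)
  }
  paste(AA_ALPHABET[idx], collapse = "")
}

#' Generate labeled synthetic sequences
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `id`, `residues`, `label` (+1 positives
#'   first, then -1 negatives), reproducible per seed.
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  comp <- spec_compositions(spec)
  theta <- default_properties()$theta
  withr::with_seed(spec$seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   spec$n_pos + spec$n_neg, replace = TRUE)
    pos <- vapply(seq_len(spec$n_pos), function(i) {
      sample_sequence(lens[i], comp$pos, spec$order_effect, theta)
    }, character(1))
    neg <- vapply(seq_len(spec$n_neg), function(i) {
      sample_sequence(lens[spec$n_pos + i], comp$neg, 0, theta)
    }, character(1))
    tibble(
      id = c(sprintf("pos_%03d", seq_len(spec$n_pos)),
             sprintf("neg_%03d", seq_len(spec$n_neg))),
      residues = c(pos, neg),
      label = rep(c(1L, -1L), c(spec$n_pos, spec$n_neg))
    )
  })
}

# One Dirichlet draw per position: concentration on the true residue,
# a small floor elsewhere so every component stays positive.
smear_onehot <- function(idx, concentration) {
  L <- length(idx)
  alpha <- matrix(0.1, L, 20)
  alpha[cbind(seq_len(L), idx)] <- alpha[cbind(seq_len(L), idx)] + concentration
  g <- matrix(rgamma(L * 20, shape = alpha), L, 20)
  g / rowSums(g)
}

#' Generate frequency profiles for synthetic sequences
#'
#' Each sequence's one-hot position matrix is smeared with Dirichlet noise
#' at the spec's concentration: rows remain stochastic, and as the
#' concentration grows the profile tends to one-hot so
#' [consensus_sequence()] recovers the source sequence. Optionally writes a
#' PSI-BLAST-format ASCII PSSM file per sequence.
#'
#' @param seqs Tibble from [generate_sequences()] (columns `id`, `residues`).
#' @param spec The [synthetic_spec()] that produced them.
#' @param dir Optional directory; when given, `<id>.pssm` files are written
#'   there (see [write_psiblast_pssm()]).
#' @return A named list of `frequency_profile` objects.
#' @export
generate_profiles <- function(seqs, spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed + 99991L, {
    profs <- purrr::map2(seqs$id, seqs$residues, function(id, s) {
      idx <- aa_index(aa_chars(s))
      frequency_profile(smear_onehot(idx, spec$profile_noise),
                        seq_id = id, source = "parsed_pssm")
    })
  })
  names(profs) <- seqs$id
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    purrr::walk2(profs, seqs$residues, function(p, s) {
      write_psiblast_pssm(p, s, file.path(dir, paste0(p$seq_id, ".pssm")))
    })
  }
  profs
}

#' Write a profile as a PSI-BLAST-format ASCII PSSM file
#'
#' Emits the two-block ASCII layout produced by `psiblast -out_ascii_pssm`
#' (integer log-odds block, then weighted-observed percentages), so that
#' generated fixtures exercise the same parser as real PSI-BLAST output.
#' Percentages are rounded to integers; a round-trip through
#' [read_psiblast_pssm()] reproduces the profile to within that
#' quantization.
#'
#' @param profile A `frequency_profile`.
#' @param residues The query sequence (length must match the profile).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(profile, residues, path) {
  stopifnot(inherits(profile, "frequency_profile"))
  m <- profile$matrix
  chars <- aa_chars(residues)
  if (length(chars) != nrow(m)) abort_input("query length does not match profile.")
  p <- blosum62_background_vec
  logodds <- round(2 * log2(pmax(m, 1e-4) / rep(p, each = nrow(m))))
  # largest-remainder rounding: integer percentages summing to exactly 100,
  # so parsing (which renormalizes) stays within the quantization error
  perc <- t(apply(m, 1, function(row) {
    f <- 100 * row
    base <- floor(f)
    need <- 100L - as.integer(sum(base))
    if (need > 0) {
      top <- order(f - base, decreasing = TRUE)[seq_len(need)]
      base[top] <- base[top] + 1
    }
    base
  }))
  header <- paste0(
    "\nLast position-specific scoring matrix computed, weighted observed ",
    "percentages rounded down, information per position, and relative ",
    "weight of gapless real matches to pseudocounts\n",
    "            ", paste(sprintf("%3s", AA_ALPHABET), collapse = ""),
    paste(sprintf("%4s", AA_ALPHABET), collapse = "")
  )
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%5d %s  ", i, chars[i]),
           paste(sprintf("%4d", logodds[i, ]), collapse = " "), "  ",
           paste(sprintf("%4d", perc[i, ]), collapse = " "),
           sprintf("  %5.2f %9.2f", 0, 0))
  }, character(1))
  writeLines(c(header, lines, ""), path)
  invisible(path)
}

#' Generate a complete labeled feature dataset
#'
#' Runs the full pipeline on synthetic data: sequences -> Dirichlet-smeared
#' profiles -> profile-consensus sequences -> PseAAC features. The returned
#' manifest records every parameter and seed so the run can be reproduced
#' exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param lambda,omega PseAAC parameters (defaults 3 and 0.7).
#' @param props Property table.
#' @return A list with `features` (tibble: `seq_id` + feature columns),
#'   `labels` (+1/-1 vector), `sequences` (the generated tibble) and
#'   `manifest` (named list of all parameters).
#' @export
generate_dataset <- function(spec, lambda = 3, omega = 0.7,
                             props = default_properties()) {
  seqs <- generate_sequences(spec)
  profs <- generate_profiles(seqs, spec)
  cons <- purrr::map(profs, consensus_sequence)
  features <- featurize_batch(cons, lambda = lambda, omega = omega, props = props)
  manifest <- c(unclass(spec),
                list(lambda = lambda, omega = omega,
                     property_hash = property_hash(props)))
  list(features = features, labels = seqs$label, sequences = seqs,
       manifest = manifest)
}
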