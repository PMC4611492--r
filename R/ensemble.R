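#' Partition negative-sample ids into balanced subsets
#'
#' Seeded uniform shuffle followed by round-robin slicing: the `k` subsets
#' are disjoint, their union is the input, and their sizes differ by at
#' most one. Used to split a large non-DNA-binding pool into subsets each
#' roughly the size of the positive set.
#'
#' @param neg_ids Vector of negative-sample identifiers.
#' @param k Number of subsets (>= 2).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list of `k` disjoint id vectors.
#' @export
#' @examples
#' lengths(partition_negatives(paste0("n", 1:2059), k = 4, seed = 1))
partition_negatives <- function(neg_ids, k, seed = 1) {
  if (k < 2) abort_config("`k` must be >= 2.")
  if (length(neg_ids) < k) abort_input("fewer negative ids than subsets.")
  if (anyDuplicated(neg_ids)) abort_input("negative ids must be unique.")
  shuffled <- withr::with_seed(seed, sample(neg_ids))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Train a probability-averaging ensemble over negative subsets
#'
#' Trains one SVM per negative subset, each paired with the shared positive
#' set; members are independent and identically configured. Predictions
#' average the members' calibrated probabilities.
#'
#' @param pos_features Feature tibble/matrix of the shared positive samples.
#' @param neg_features_by_subset List of feature tibbles/matrices, one per
#'   negative subset (e.g. built from [partition_negatives()]).
#' @inheritParams svm_train
#' @param partition_seed Seed used to build the partition (recorded for
#'   reproducibility).
#' @param subset_assignments Optional named vector mapping negative id to
#'   member index (recorded in the manifest).
#' @return An object of class `pseaac_ensemble`.
#' @export
train_ensemble <- function(pos_features, neg_features_by_subset,
                           C = 8192, gamma = 8, partition_seed = NA_integer_,
                           subset_assignments = NULL) {
  if (length(neg_features_by_subset) < 2) {
    abort_input("an ensemble needs at least 2 negative subsets.")
  }
  pos <- feature_matrix(pos_features)
  members <- purrr::map(neg_features_by_subset, function(neg) {
    neg <- feature_matrix(neg)
    if (nrow(neg) == 0) abort_input("empty negative subset.")
    svm_train(rbind(pos, neg), c(rep(1L, nrow(pos)), rep(-1L, nrow(neg))),
              C = C, gamma = gamma)
  })
  structure(list(members = unname(members), partition_seed = partition_seed,
                 subset_assignments = subset_assignments),
            class = "pseaac_ensemble")
}

#' Predict with a negative-subset ensemble
#'
#' Each member produces a calibrated probability of the positive class; the
#' ensemble probability is their arithmetic mean and the predicted label is
#' positive iff the mean is `>= 0.5` (exact ties count as positive, by
#' convention).
#'
#' @param model A `pseaac_ensemble`.
#' @param features Feature tibble or matrix.
#' @return A tibble with columns `seq_id` (when available), `prob` (mean
#'   member probability) and `label` (`+1`/`-1`); per-member probabilities
#'   are attached as attribute `"member_probs"`.
#' @export
predict_ensemble <- function(model, features) {
  stopifnot(inherits(model, "pseaac_ensemble"))
  x <- feature_matrix(features)
  probs <- vapply(model$members, function(m) predict(m, x, type = "probability"),
                  numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x))
  p <- rowMeans(probs)
  out <- tibble(
    seq_id = if (is.data.frame(features) && "seq_id" %in% names(features))
      features$seq_id else rownames(x) %||% as.character(seq_len(nrow(x))),
    prob = p,
    label = ifelse(p >= 0.5, 1L, -1L)
  )
  attr(out, "member_probs") <- probs
  out
}

#' @export
print.pseaac_ensemble <- function(x, ...) {
  cat("<pseaac_ensemble> ", length(x$members), " members (partition seed ",
      x$partition_seed, ")\n", sep = "")
  invisible(x)
}

#' @rdname train_ensemble
#' @param x A `pseaac_ensemble`.
#' @param ... Unused.
#' @export
glance.pseaac_ensemble <- function(x, ...) {
  tibble(members = length(x$members),
         partition_seed = x$partition_seed,
         C = x$members[[1]]$C, gamma = x$members[[1]]$gamma)
}
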