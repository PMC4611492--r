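# Kernel matrix between row-sets a and b.
kernel_matrix <- function(a, b, gamma, kernel = "radial") {
  if (kernel == "linear") return(a %*% t(b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

#' Train the RBF support vector classifier
#'
#' Fits a C-SVM (libsvm via e1071) on a PseAAC feature matrix. Defaults are
#' the grid-search optima used throughout the package, `C = 8192` and
#' `gamma = 8` with the radial kernel `K(x, y) = exp(-gamma ||x - y||^2)`.
#' The fitted model stores its support vectors, signed dual coefficients
#' (oriented so positive decision values mean the positive, DNA-binding
#' class) and the full training feature matrix (needed for
#' [discriminant_weights()]); decision values are recomputed directly from
#' these, verified against the libsvm output at training time, so a model
#' restored from disk ([read_model()]) predicts identically. Class
#' probabilities come from a Platt-style sigmoid fitted on the training
#' decision values.
#'
#' @param features Feature tibble (from [featurize_batch()]) or numeric
#'   matrix; a `seq_id`/`label` column is dropped automatically.
#' @param labels Class labels in `{-1, +1}` (+1 = DNA-binding).
#' @param C Soft-margin penalty (> 0).
#' @param gamma RBF width (> 0).
#' @param kernel `"radial"` (default) or `"linear"` (used for consistency
#'   checks against the primal weight vector).
#' @param meta Optional named list recorded with the model (e.g. `lambda`,
#'   `omega`, property-table hash).
#' @return An object of class `pseaac_svm`.
#' @export
svm_train <- function(features, labels, C = 8192, gamma = 8,
                      kernel = c("radial", "linear"), meta = list()) {
  kernel <- match.arg(kernel)
  x <- feature_matrix(features)
  y <- normalize_labels(labels)
  if (!is.numeric(C) || C <= 0 || !is.numeric(gamma) || gamma <= 0) {
    abort_config("`C` and `gamma` must be positive.")
  }
  if (any(!is.finite(x))) abort_input("features contain non-finite values.")
  if (length(unique(y)) < 2) abort_input("training data must contain both classes.")
  if (nrow(x) != length(y)) abort_input("features and labels differ in length.")

  fit <- e1071::svm(x = x, y = factor(y, levels = c(1, -1)), scale = FALSE,
                    kernel = kernel, cost = C, gamma = gamma)
  sv <- fit$SV
  coefs <- as.numeric(fit$coefs)
  rho <- fit$rho
  # orient the decision function so positive favors class +1
  s <- if (colnames(fit$decision.values)[1] == "1/-1") 1 else -1
  coefs <- s * coefs
  rho <- s * rho
  dec <- as.numeric(kernel_matrix(x, sv, gamma, kernel) %*% coefs - rho)
  dec_lib <- s * as.numeric(attr(predict(fit, x, decision.values = TRUE),
                                 "decision.values"))
  if (max(abs(dec - dec_lib)) > 1e-6) {
    abort("internal error: direct decision values disagree with libsvm.")
  }
  platt <- fit_platt(dec, y)
  structure(
    list(x = x, y = y, C = C, gamma = gamma, kernel = kernel,
         sv = sv, coefs = coefs, rho = rho, index = fit$index,
         platt = platt, feature_names = colnames(x), meta = meta),
    class = "pseaac_svm"
  )
}

# Sigmoid calibration P(+1 | f) = plogis(a + b f) fitted on training
# decision values (deterministic; no internal cross-validation).
fit_platt <- function(dec, y) {
  df <- data.frame(y01 = as.integer(y == 1), dec = dec)
  fit <- suppressWarnings(glm(y01 ~ dec, data = df, family = binomial(),
                              control = list(maxit = 100)))
  c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
}

#' Predict with a trained PseAAC SVM
#'
#' @param object A `pseaac_svm`.
#' @param newdata Feature tibble or matrix with the model's feature columns.
#' @param type `"class"` (labels in `{-1, +1}`; decision value >= 0 maps to
#'   +1), `"decision"` (raw decision values) or `"probability"`
#'   (Platt-calibrated P(+1)).
#' @param ... Unused.
#' @return A numeric (or integer) vector, one value per row of `newdata`.
#' @export
predict.pseaac_svm <- function(object, newdata,
                               type = c("class", "decision", "probability"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata)
  if (ncol(x) != ncol(object$sv)) {
    abort_input(paste0("feature dimension mismatch: model expects ",
                       ncol(object$sv), ", got ", ncol(x), "."))
  }
  dec <- as.numeric(kernel_matrix(x, object$sv, object$gamma, object$kernel) %*%
                      object$coefs - object$rho)
  switch(type,
         decision = dec,
         probability = plogis(object$platt["a"] + object$platt["b"] * dec),
         class = ifelse(dec >= 0, 1L, -1L))
}

#' Signed dual coefficients of every training sample
#'
#' Length-N vector `A` with `A_i = y_i alpha_i` for support samples and 0
#' otherwise, oriented so positive entries belong to the positive class.
#' Magnitudes are bounded by `C`.
#'
#' @param model A `pseaac_svm`.
#' @return Numeric vector, one entry per training sample.
#' @export
dual_coefficients <- function(model) {
  stopifnot(inherits(model, "pseaac_svm"))
  A <- numeric(nrow(model$x))
  A[model$index] <- model$coefs
  A
}

#' Discriminant weight vector
#'
#' Projects the per-sample dual weights through the training feature matrix:
#' `W_j = sum_i A_i M_ij`, where `A` are the signed dual coefficients and
#' `M` the training features. The sign of `W_j` indicates which class
#' feature `j` favors (positive = DNA-binding); for a linear kernel `W` is
#' exactly the primal weight vector.
#'
#' @param model A trained `pseaac_svm`.
#' @return A tibble with columns `feature` and `weight`.
#' @export
discriminant_weights <- function(model) {
  stopifnot(inherits(model, "pseaac_svm"))
  A <- dual_coefficients(model)
  tibble(feature = model$feature_names %||% paste0("f", seq_len(ncol(model$x))),
         weight = as.numeric(t(A) %*% model$x))
}

#' @export
print.pseaac_svm <- function(x, ...) {
  cat("<pseaac_svm> ", x$kernel, " kernel, C = ", x$C, ", gamma = ", x$gamma,
      ", ", nrow(x$x), " samples, ", length(x$index), " SVs\n", sep = "")
  invisible(x)
}

#' Tidy methods for fitted PseAAC SVMs
#'
#' `tidy()` returns one row per training sample with its label and signed
#' dual coefficient; `glance()` returns a one-row model summary.
#'
#' @param x A `pseaac_svm`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pseaac_svm <- function(x, ...) {
  tibble(sample = rownames(x$x) %||% as.character(seq_len(nrow(x$x))),
         label = x$y, dual_coefficient = dual_coefficients(x))
}

#' @rdname tidy.pseaac_svm
#' @export
glance.pseaac_svm <- function(x, ...) {
  tibble(kernel = x$kernel, C = x$C, gamma = x$gamma,
         n = nrow(x$x), n_sv = length(x$index),
         n_features = ncol(x$x))
}

#' Grid search for C and gamma
#'
#' Cross-validated accuracy over a `C x gamma` grid; the default grids are
#' the customary powers of two, `C = 2^(-5..15)` and `gamma = 2^(-15..3)`,
#' which contain the package defaults `(8192, 8)`. Ties are broken toward
#' smaller `C`, then smaller `gamma`. Fold assignment is stratified by
#' class and derived from `seed` only.
#'
#' @inheritParams svm_train
#' @param C_grid,gamma_grid Candidate values.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @return A list with the selected `C`, `gamma`, the winning `accuracy`,
#'   and `results`, a tibble of all grid points.
#' @export
grid_search <- function(features, labels, C_grid = 2^(-5:15),
                        gamma_grid = 2^(-15:3), folds = 5, seed = 1) {
  x <- feature_matrix(features)
  y <- normalize_labels(labels)
  n <- nrow(x)
  if (length(C_grid) == 0 || length(gamma_grid) == 0) {
    abort_config("parameter grids must be nonempty.")
  }
  if (folds < 2) abort_config("`folds` must be >= 2.")
  if (n < folds) abort_input("fewer samples than folds.")
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  grid <- tidyr::expand_grid(C = sort(C_grid), gamma = sort(gamma_grid))
  acc <- purrr::pmap_dbl(grid, function(C, gamma) {
    correct <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) {
        pred <- rep(as.integer(names(which.max(table(y[tr])))), sum(!tr))
      } else {
        m <- svm_train(x[tr, , drop = FALSE], y[tr], C = C, gamma = gamma)
        pred <- predict(m, x[!tr, , drop = FALSE])
      }
      correct <- correct + sum(pred == y[!tr])
    }
    correct / n
  })
  results <- dplyr::mutate(grid, cv_accuracy = acc)
  best <- results |>
    dplyr::arrange(dplyr::desc(.data$cv_accuracy), .data$C, .data$gamma) |>
    dplyr::slice(1)
  list(C = best$C, gamma = best$gamma, accuracy = best$cv_accuracy,
       results = results)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Singles out each sample in turn, trains on the remaining `N - 1` and
#' predicts the held-out sample; the `N` predictions are accumulated into a
#' confusion matrix and ROC/AUC over the held-out decision values.
#' Deterministic given the inputs.
#'
#' @inheritParams svm_train
#' @return An `eval_report` whose `predictions` field holds the per-sample
#'   held-out label, decision score and prediction.
#' @export
jackknife <- function(features, labels, C = 8192, gamma = 8) {
  x <- feature_matrix(features)
  y <- normalize_labels(labels)
  n <- nrow(x)
  if (n < 3) abort_input("jackknife needs at least 3 samples.")
  if (min(table(y)) < 2) {
    abort_input("each class needs >= 2 samples so no holdout empties a class.")
  }
  dec <- vapply(seq_len(n), function(i) {
    m <- svm_train(x[-i, , drop = FALSE], y[-i], C = C, gamma = gamma)
    predict(m, x[i, , drop = FALSE], type = "decision")
  }, numeric(1))
  eval_report_from_predictions(y, dec, ifelse(dec >= 0, 1L, -1L))
}
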