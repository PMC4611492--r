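test_that("training separates separable data and satisfies dual constraints", {
  set.seed(4)
  feats <- separable_features()
  y <- separable_labels()
  m <- svm_train(feats, y, C = 10, gamma = 1)
  expect_equal(as.integer(predict(m, feats)), y)

  A <- dual_coefficients(m)
  expect_length(A, 8)
  expect_true(all(abs(A) <= 10 + 1e-8))
  nz <- A != 0
  expect_true(all(sign(A[nz]) == y[nz]))
  expect_equal(sum(A), 0, tolerance = 1e-8)
})

test_that("duplicating the training set leaves the decision function stable", {
  set.seed(8)
  feats <- separable_features(6, gap = 2)
  y <- separable_labels(6)
  m1 <- svm_train(feats, y, C = 4, gamma = 0.5)
  m2 <- svm_train(dplyr::bind_rows(feats, feats), c(y, y), C = 4, gamma = 0.5)
  grid <- tibble::tibble(f1 = seq(-3, 3, length.out = 11), f2 = 0)
  expect_equal(predict(m1, grid, type = "decision"),
               predict(m2, grid, type = "decision"), tolerance = 0.2)
  expect_equal(predict(m1, grid), predict(m2, grid))
})

test_that("the RBF kernel solves XOR where a linear machine cannot", {
  xor <- tibble::tibble(
    f1 = c(1, -1, 1, -1) + rep(c(0.01, -0.01), 2),
    f2 = c(1, -1, -1, 1)
  )
  y <- c(1L, 1L, -1L, -1L)
  rbf <- svm_train(xor, y, C = 100, gamma = 1)
  expect_equal(as.integer(predict(rbf, xor)), y)
  lin <- svm_train(xor, y, C = 100, gamma = 1, kernel = "linear")
  expect_gt(sum(as.integer(predict(lin, xor)) != y), 0)
})

test_that("training-time decision values agree with an independent SVM fit", {
  skip_if_not_installed("kernlab")
  set.seed(12)
  x <- matrix(rnorm(60), 30, 2)
  y <- ifelse(x[, 1] + 0.3 * rnorm(30) > 0, 1L, -1L)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  m <- svm_train(x, y, C = 2, gamma = 1.5)
  k <- kernlab::ksvm(x, factor(y), type = "C-svc", C = 2,
                     kernel = "rbfdot", kpar = list(sigma = 1.5), scaled = FALSE)
  dec_k <- kernlab::predict(k, x, type = "decision")[, 1]
  # orient kernlab's decision values toward class +1
  if (cor(dec_k, predict(m, x, type = "decision")) < 0) dec_k <- -dec_k
  expect_equal(as.integer(predict(m, x)), as.integer(sign(dec_k)))
})

test_that("grid search honors ties, seeds, and contains the default optimum", {
  set.seed(6)
  feats <- separable_features(5)
  y <- separable_labels(5)
  g <- grid_search(feats, y, C_grid = 1, gamma_grid = 1, folds = 2)
  expect_equal(g$C, 1)
  expect_equal(g$gamma, 1)

  g <- grid_search(feats, y, C_grid = c(1, 10), gamma_grid = c(0.5, 1),
                   folds = 2, seed = 3)
  expect_equal(g$accuracy, 1)
  # perfect accuracy everywhere on separable data: tie-break to smallest pair
  expect_equal(g$C, 1)
  expect_equal(g$gamma, 0.5)

  expect_true(any(abs(2^(-5:15) - 8192) < 1e-9))
  expect_true(any(abs(2^(-15:3) - 8.0) < 1e-9))

  expect_error(grid_search(feats[1:3, ], y[1:3], folds = 5), "fewer samples")
})

test_that("jackknife equals a naive leave-one-out reimplementation", {
  # 4 well-separated samples: perfect metrics
  feats <- tibble::tibble(f1 = c(5, 5.1, -5, -5.1), f2 = 0)
  y <- c(1L, 1L, -1L, -1L)
  rep <- jackknife(feats, y, C = 10, gamma = 1)
  expect_equal(rep$acc, 100)
  expect_equal(rep$mcc, 1)
  expect_equal(rep$auc, 1)

  # N = 6 toy set: identical counts to a from-scratch loop over e1071
  set.seed(31)
  x <- matrix(rnorm(12, sd = 2), 6, 2)
  y <- c(1L, 1L, 1L, -1L, -1L, -1L)
  rep <- jackknife(x, y, C = 2, gamma = 0.7)
  naive_pred <- vapply(1:6, function(i) {
    fit <- e1071::svm(x = x[-i, ], y = factor(y[-i], levels = c(1, -1)),
                      scale = FALSE, cost = 2, gamma = 0.7)
    as.integer(as.character(predict(fit, x[i, , drop = FALSE])))
  }, integer(1))
  expect_equal(rep$tp, sum(y == 1 & naive_pred == 1))
  expect_equal(rep$tn, sum(y == -1 & naive_pred == -1))
  expect_equal(rep$fp, sum(y == -1 & naive_pred == 1))
  expect_equal(rep$fn, sum(y == 1 & naive_pred == -1))

  expect_error(jackknife(x[1:3, ], c(1L, 1L, -1L)), "class")
})

test_that("jackknife on permuted labels sits near chance", {
  set.seed(77)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- sample(rep(c(1L, -1L), 20))
  rep <- jackknife(x, y, C = 8, gamma = 0.5)
  expect_gt(rep$auc, 0.25)
  expect_lt(rep$auc, 0.75)
})

test_that("metric closed forms agree with the textbook definitions", {
  r <- metrics_from_counts(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(c(r$sn, r$sp, r$acc, r$mcc), c(100, 100, 100, 1))

  set.seed(15)
  for (i in 1:1000) {
    cts <- sample(0:60, 4, replace = TRUE) + c(1, 1, 0, 0)
    r <- metrics_from_counts(cts[1], cts[2], cts[3], cts[4])
    tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
    expect_equal(r$sn, 100 * tp / (tp + fn))
    expect_equal(r$sp, 100 * tn / (tn + fp))
    expect_equal(r$acc, 100 * (tp + tn) / sum(cts))
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0) expect_equal(r$mcc, (tp * tn - fp * fn) / den)
  }

  expect_warning(r <- metrics_from_counts(tp = 0, tn = 3, fp = 0, fn = 2),
                 "MCC")
  expect_equal(r$mcc, 0)
  expect_error(metrics_from_counts(0, 5, 0, 0), "positive")
})

test_that("confusion counts are uniquely recoverable from printed rates", {
  cts <- counts_from_rates(75.62, 77.45, 525, 550)
  expect_equal(cts, list(tp = 397, fn = 128, tn = 426, fp = 124))
  # 77.41 only truncates (72/93 = 77.419...): both conventions accepted
  cts <- counts_from_rates(77.41, 62.37, 93, 93)
  expect_equal(cts, list(tp = 72, fn = 21, tn = 58, fp = 35))
  expect_error(counts_from_rates(50.37, 50, 10, 10), "no integer")
})

test_that("ROC/AUC matches the pairwise oracle and ranking limits", {
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, -1, -1))$auc, 0)
  expect_equal(roc_auc(rep(1, 10), rep(c(1, -1), 5))$auc, 0.5)

  set.seed(19)
  scores <- round(rnorm(100), 1)  # rounding forces ties
  labels <- rep(c(1, -1), each = 50)
  got <- roc_auc(scores, labels)
  expect_equal(got$auc, oracle_auc(scores, labels))

  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores), labels)$auc, got$auc)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels)$auc, got$auc,
               tolerance = 1e-12)

  # curve starts at (0,0), ends at (1,1), monotone in both coordinates
  expect_equal(unlist(got$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(got$roc[nrow(got$roc), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(got$roc$fpr) >= 0))
  expect_true(all(diff(got$roc$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(80)
  labels <- ifelse(scores + rnorm(80) > 0, 1, -1)
  if (length(unique(labels)) < 2) labels[1] <- -labels[1]
  got <- roc_auc(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<", levels = c(-1, 1))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("discriminant weights point along the separating direction", {
  feats <- tibble::tibble(f1 = c(1, 1.1, 0.9, -1, -1.1, -0.9))
  y <- c(1L, 1L, 1L, -1L, -1L, -1L)
  m <- svm_train(feats, y, C = 10, gamma = 1)
  w <- discriminant_weights(m)
  expect_equal(nrow(w), 1)
  expect_gt(w$weight, 0)

  # linear kernel: W is the primal weight vector, so x W - rho reproduces
  # the decision values
  set.seed(25)
  x <- matrix(rnorm(40), 20, 2)
  y <- ifelse(x[, 1] - x[, 2] > 0, 1L, -1L)
  if (min(table(y)) < 2) y[1:2] <- c(1L, -1L)
  lin <- svm_train(x, y, C = 1, gamma = 1, kernel = "linear")
  W <- discriminant_weights(lin)$weight
  expect_equal(as.numeric(x %*% W - lin$rho),
               predict(lin, x, type = "decision"), tolerance = 1e-6)
})

test_that("models survive a JSON round trip", {
  set.seed(33)
  feats <- separable_features(5, gap = 2)
  y <- separable_labels(5)
  m <- svm_train(feats, y, C = 8, gamma = 2,
                 meta = list(lambda = 3, omega = 0.7))
  tf <- tempfile(fileext = ".json")
  write_model(m, tf)
  m2 <- read_model(tf)
  newx <- tibble::tibble(f1 = rnorm(5), f2 = rnorm(5))
  expect_equal(predict(m2, newx, type = "decision"),
               predict(m, newx, type = "decision"), tolerance = 1e-12)
  expect_equal(predict(m2, newx, type = "probability"),
               predict(m, newx, type = "probability"), tolerance = 1e-12)
  expect_equal(m2$meta$lambda, 3)
  expect_equal(discriminant_weights(m2), discriminant_weights(m),
               tolerance = 1e-12)
})

test_that("tidiers summarize models and reports", {
  feats <- separable_features()
  y <- separable_labels()
  m <- svm_train(feats, y, C = 10, gamma = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 8)
  expect_named(td, c("sample", "label", "dual_coefficient"))
  expect_equal(glance(m)$n_sv, length(m$index))

  rep <- metrics_from_counts(10, 10, 2, 3)
  expect_equal(nrow(tidy(rep)), 5)
  expect_equal(glance(rep)$acc, rep$acc)
})
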