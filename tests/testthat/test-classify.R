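# KNN distance score, LOO cross-validation, permutation significance.

test_that("distance score matches hand-enumerated cases", {
  expect_equal(knn_distance_score(c(0), matrix(c(0, 3, 4), ncol = 1),
                                  k = 1), 0)
  expect_equal(knn_distance_score(c(0), matrix(c(3, 4), ncol = 1),
                                  k = 2), 7)
  others <- matrix(rnorm(12), ncol = 2)
  x <- rnorm(2)
  total <- sum(sqrt(rowSums(sweep(others, 2, x)^2)))
  expect_equal(knn_distance_score(x, others, k = nrow(others)), total)
  expect_error(knn_distance_score(x, others, k = 7), "k must")
  expect_error(knn_distance_score(x, others[0, , drop = FALSE], 1),
               "empty")
})

test_that("LOO-KNN equals the exhaustive oracle, including even-K ties", {
  set.seed(11)
  for (r in 1:8) {
    n <- sample(6:12, 1)
    d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n)
    labels <- factor(sample(rep(c("healthy", "patient"), length.out = n)),
                     levels = c("healthy", "patient"))
    feats <- list(features = X, labels = labels,
                  subjects = sprintf("s%02d", seq_len(n)))
    for (K in 1:3) {
      cv <- loo_cv(feats, K)
      expect_identical(cv$predictions$predicted, naive_loo(X, labels, K))
    }
  }
  # engineered even-K tie: 1-D values where the two nearest neighbours
  # of 0.0 disagree -> the closest one must cast the deciding vote
  X <- matrix(c(0, 0.1, -0.2, 5, 5.1, 5.2), ncol = 1)
  labels <- factor(c("healthy", "patient", "healthy",
                     "patient", "patient", "healthy"),
                   levels = c("healthy", "patient"))
  cv <- loo_cv(list(features = X, labels = labels,
                    subjects = letters[1:6]), K = 2)
  # subject 1's neighbours at K=2: 0.1 (patient), -0.2 (healthy): tie,
  # nearest (0.1) decides
  expect_identical(cv$predictions$predicted[1], "patient")
})

test_that("metrics decompose exactly and separable data scores perfectly", {
  set.seed(3)
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 50, 0.1), 5))
  labels <- factor(rep(c("healthy", "patient"), each = 5),
                   levels = c("healthy", "patient"))
  cv <- loo_cv(list(features = X, labels = labels,
                    subjects = letters[1:10]), K = 3)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(cv$sensitivity, 1)
  # accuracy == (TP + TN)/n on an imperfect case
  X2 <- matrix(rnorm(20), ncol = 2)
  cv2 <- loo_cv(list(features = X2, labels = labels,
                     subjects = letters[1:10]), K = 1)
  tp <- sum(cv2$predictions$predicted == "patient" &
              cv2$predictions$label == "patient")
  tn <- sum(cv2$predictions$predicted == "healthy" &
              cv2$predictions$label == "healthy")
  expect_equal(cv2$accuracy, (tp + tn) / 10)
  expect_error(loo_cv(list(features = X, labels = labels,
                           subjects = letters[1:10]), K = 12), "K must")
  expect_error(loo_cv(list(features = X[1:3, ],
                           labels = factor(c("healthy", "patient",
                                             "patient"),
                                           levels = c("healthy",
                                                      "patient")),
                           subjects = letters[1:3]), K = 1),
               ">= 2 subjects")
})

test_that("no leakage: each fold's prediction uses only the other subjects", {
  set.seed(5)
  X <- matrix(rnorm(16 * 3), 16)
  labels <- factor(rep(c("healthy", "patient"), 8),
                   levels = c("healthy", "patient"))
  feats <- list(features = X, labels = labels,
                subjects = sprintf("s%02d", 1:16))
  cv <- loo_cv(feats, K = 3)
  for (i in c(1, 7, 16)) {
    d <- sqrt(colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2))
    nn <- order(d)[1:3]
    votes <- as.character(labels[-i])[nn]
    want <- if (sum(votes == "patient") * 2 > 3) "patient" else "healthy"
    expect_identical(cv$predictions$predicted[i], want)
  }
})

test_that("permutation significance is calibrated and deterministic", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 40, 0.1), 20, 2))
  labels <- factor(rep(c("healthy", "patient"), each = 20),
                   levels = c("healthy", "patient"))
  feats <- list(features = X, labels = labels,
                subjects = sprintf("s%02d", 1:40))
  sig <- significance(feats, K = 3, n_perm = 199, seed = 4)
  expect_equal(sig$p_value, 1 / 200)           # beats every permutation
  expect_identical(sig$p_value,
                   significance(feats, K = 3, n_perm = 199,
                                seed = 4)$p_value)
  # shuffled-label null accuracy centred at chance
  expect_lt(abs(mean(sig$null_accuracy) - 0.5),
            3 * stats::sd(sig$null_accuracy) / sqrt(199))
  expect_error(significance(feats, K = 3, n_perm = 10), "n_perm")
})

test_that("permutation p-values are uniform under a pure-noise null", {
  set.seed(31)
  pvals <- vapply(1:50, function(i) {
    X <- matrix(rnorm(12 * 4), 12)
    labels <- factor(rep(c("healthy", "patient"), each = 6),
                     levels = c("healthy", "patient"))
    significance(list(features = X, labels = labels,
                      subjects = letters[1:12]),
                 K = 3, n_perm = 199, seed = i)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
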