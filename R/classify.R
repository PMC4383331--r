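# KNN discrimination on Stockwell features with leave-one-out
# cross-validation.
#
# Voting rule: the K nearest training vectors vote by majority label;
# when K is even and the vote ties, the single closest neighbour casts
# the deciding vote.  Distance ties are broken by stable input order
# (subjects are kept in their supplied order), so results are
# deterministic.  Metrics use healthy as the negative class and
# patient as the positive class.

#' KNN distance score
#'
#' Sum of the Euclidean distances from `x_i` to its `k` nearest rows of
#' `others` (which must not contain `x_i`'s own copies unless that is
#' intended; a duplicate at distance zero is legal and scores 0 for
#' k = 1).
#'
#' @param x_i numeric feature vector.
#' @param others numeric matrix, one candidate per row.
#' @param k number of nearest neighbours summed; `1 <= k <= nrow(others)`.
#' @return non-negative scalar.
#' @export
knn_distance_score <- function(x_i, others, k) {
  if (!is.matrix(others)) others <- matrix(others, ncol = length(x_i))
  if (nrow(others) < 1)
    stop_config("knn_distance_score: 'others' is empty")
  if (k < 1 || k > nrow(others))
    stop_config("knn_distance_score: k must lie in [1, %d] (got %d)",
                nrow(others), k)
  d <- sqrt(colSums((t(others) - x_i)^2))
  sum(sort(d, method = "radix")[seq_len(k)])
}

# LOO predictions from a precomputed distance matrix (rows/cols in
# subject order).  Shared by loo_cv() and significance() so label
# permutations do not recompute distances.
loo_predict_from_dist <- function(D, labels, K) {
  loo_predict_multi_k(D, labels, K)[, 1]
}

# Multi-K variant: one neighbour ordering per held-out subject serves
# every K (the grid search scans K).  Majority vote with the closest
# neighbour casting the deciding vote on even-K ties.  Returns an
# n x length(Ks) character matrix.
loo_predict_multi_k <- function(D, labels, Ks) {
  n <- nrow(D)
  k_top <- max(Ks)
  lab_chr <- as.character(labels)
  out <- matrix("", n, length(Ks))
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nn <- order(d)[seq_len(k_top)]      # stable for ties: input order
    is_pat <- lab_chr[nn] == "patient"
    pat_cum <- cumsum(is_pat)
    for (j in seq_along(Ks)) {
      k <- Ks[j]
      pat <- pat_cum[k]
      out[i, j] <- if (pat * 2 > k) "patient"
        else if (pat * 2 < k) "healthy"
        else lab_chr[nn[1]]             # even-K tie: casting vote
    }
  }
  out
}

#' Leave-one-out cross-validated KNN classification
#'
#' Each subject is predicted from all remaining subjects' feature
#' vectors (every vector of the held-out subject is withheld).  Returns
#' per-subject predictions and distance scores plus accuracy,
#' specificity (healthy = negative class) and sensitivity.
#'
#' @param feats a `"tffo_features"` object from [extract_features()],
#'   or a list with `features` (matrix), `labels` (factor with levels
#'   healthy, patient) and optionally `subjects`.
#' @param K number of voting neighbours (`1 <= K <= n - 1`).
#' @return an object of class `"tffo_cv"`.
#' @export
loo_cv <- function(feats, K) {
  X <- feats$features
  labels <- feats$labels
  n <- nrow(X)
  if (any(table(labels) < 2))
    stop_config("loo_cv: each class needs >= 2 subjects (leave-one-out would empty a class)")
  if (K < 1 || K > n - 1)
    stop_config("loo_cv: K must lie in [1, %d] (got %d)", n - 1, K)
  D <- as.matrix(stats::dist(X))
  pred <- loo_predict_from_dist(D, labels, K)
  score <- vapply(seq_len(n), function(i)
    knn_distance_score(X[i, ], X[-i, , drop = FALSE], K), 0)
  cv_result(labels, pred, score, feats$subjects %||% rownames(X), K)
}

cv_result <- function(labels, pred, score, subjects, K) {
  correct <- pred == as.character(labels)
  tp <- sum(pred == "patient" & labels == "patient")
  tn <- sum(pred == "healthy" & labels == "healthy")
  structure(
    list(predictions = data.frame(
           subject_id = subjects %||% seq_along(labels),
           label = as.character(labels), predicted = pred,
           distance_score = score),
         accuracy = mean(correct),
         specificity = tn / sum(labels == "healthy"),
         sensitivity = tp / sum(labels == "patient"),
         n_subjects = length(labels), K = K),
    class = "tffo_cv")
}

#' @export
print.tffo_cv <- function(x, ...) {
  cat(sprintf("<tffo_cv> n = %d, K = %d: accuracy %.3f, specificity %.3f, sensitivity %.3f\n",
              x$n_subjects, x$K, x$accuracy, x$specificity, x$sensitivity))
  invisible(x)
}

#' Permutation significance of a cross-validated accuracy
#'
#' Shuffles the group labels `n_perm` times, recomputes the LOO-KNN
#' accuracy on the unchanged distance matrix, and reports the
#' plus-one-corrected fraction of permutations reaching the observed
#' accuracy.
#'
#' @inheritParams loo_cv
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draw.
#' @return list with `p_value`, `observed` accuracy and the permutation
#'   accuracies `null_accuracy`.
#' @export
significance <- function(feats, K, n_perm = 199, seed = 1) {
  if (n_perm < 100)
    stop_config("significance: n_perm must be >= 100")
  X <- feats$features
  labels <- feats$labels
  D <- as.matrix(stats::dist(X))
  obs <- mean(loo_predict_from_dist(D, labels, K) ==
                as.character(labels))
  null_acc <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    lab_b <- sample(labels)
    mean(loo_predict_from_dist(D, lab_b, K) == as.character(lab_b))
  }, 0))
  list(p_value = (1 + sum(null_acc >= obs)) / (n_perm + 1),
       observed = obs, null_accuracy = null_acc)
}
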