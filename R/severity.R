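# Disease-severity analysis: distance of each subject's Stockwell
# feature vector to the healthy-group centroid, an exponential
# hospitalization scale, closed-form ridge regression of rank on the
# (log-) transformed distance, and severe-half rank checks.

#' Distance-to-healthy-centroid severity feature
#'
#' Euclidean distance from each subject's feature vector to the
#' element-wise mean feature vector of the healthy group; for healthy
#' subjects their own vector is excluded from the centroid.  The
#' transformed distance (default natural log; distances are strictly
#' positive for noisy data) is the regression predictor.
#'
#' @param feats a `"tffo_features"` object (see [extract_features()]).
#' @param transform `"log"` (default) or `"identity"`.
#' @return data frame: subject_id, group, distance,
#'   transformed_distance.
#' @export
severity_distance <- function(feats, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  X <- feats$features
  labels <- as.character(feats$labels)
  healthy <- which(labels == "healthy")
  if (length(healthy) < 2)
    stop_config("severity_distance: need >= 2 healthy subjects")
  d <- vapply(seq_len(nrow(X)), function(i) {
    ref <- setdiff(healthy, i)
    sqrt(sum((X[i, ] - colMeans(X[ref, , drop = FALSE]))^2))
  }, 0)
  td <- switch(transform, log = log(d), identity = d)
  data.frame(subject_id = feats$subjects, group = labels,
             distance = d, transformed_distance = td)
}

#' Exponential hospitalization scale
#'
#' Maps a documented hospitalization count to its rank on the
#' exponential scale (1), (2), (3-4), (5-7), (8-15), (16+).
#'
#' @param n hospitalization count(s), each >= 1.
#' @return integer rank(s) in 1..6.
#' @export
hospitalization_rank <- function(n) {
  if (any(!is.finite(n)) || any(n < 1))
    stop_config("hospitalization_rank: counts must be >= 1")
  findInterval(n, c(1, 2, 3, 5, 8, 16))
}

#' Ridge regression of severity rank on the distance feature
#'
#' Closed-form one-predictor ridge: with centred x and y, the slope is
#' `sum(xy) / (sum(x^2) + penalty)`.  Reports both the in-sample R^2
#' and the leave-one-out R^2 (each held-out patient predicted by a
#' model refit without it) to expose optimism.  When `penalty = NULL`
#' it is chosen by leave-one-out CV over a log-spaced grid.
#'
#' @param x transformed distance per patient.
#' @param ranks severity ranks (e.g. [hospitalization_rank()]).
#' @param penalty ridge penalty >= 0, or `NULL` to select by LOO.
#' @return list of class `"tffo_ridge"`: coefficients, penalty,
#'   `r_squared` (in-sample), `r_squared_loo`, fitted values.
#' @export
fit_severity <- function(x, ranks, penalty = NULL) {
  y <- as.numeric(ranks)
  if (length(x) != length(y))
    stop_config("fit_severity: x and ranks lengths differ")
  if (length(x) < 2)
    stop_config("fit_severity: need >= 2 patients")
  if (stats::var(x) == 0)
    stop_config("fit_severity: zero-variance predictor")
  ridge_fit <- function(x, y, lambda) {
    xm <- mean(x); ym <- mean(y)
    b <- sum((x - xm) * (y - ym)) / (sum((x - xm)^2) + lambda)
    c(intercept = ym - b * xm, slope = b)
  }
  loo_sse <- function(lambda) {
    sum(vapply(seq_along(x), function(i) {
      cf <- ridge_fit(x[-i], y[-i], lambda)
      (y[i] - (cf[1] + cf[2] * x[i]))^2
    }, 0))
  }
  if (is.null(penalty)) {
    grid <- c(0, sum((x - mean(x))^2) * 10^seq(-4, 1, length.out = 21))
    penalty <- grid[which.min(vapply(grid, loo_sse, 0))]
  }
  if (penalty < 0) stop_config("fit_severity: penalty must be >= 0")
  cf <- ridge_fit(x, y, penalty)
  fitted <- cf[1] + cf[2] * x
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  r2_loo <- 1 - loo_sse(penalty) / ss_tot
  structure(list(coefficients = cf, penalty = penalty,
                 r_squared = r2, r_squared_loo = r2_loo,
                 fitted = fitted, residuals = y - fitted),
            class = "tffo_ridge")
}

#' @export
print.tffo_ridge <- function(x, ...) {
  cat(sprintf("<tffo_ridge> penalty %.4g: slope %.4g, R^2 %.3f (LOO %.3f)\n",
              x$penalty, x$coefficients["slope"], x$r_squared,
              x$r_squared_loo))
  invisible(x)
}

#' Severe-half concordance check
#'
#' Counts how many of the `top_k` patients ranked by a clinical
#' covariate fall in the "severe half" (the top `ceiling(n/2)`) of the
#' distance-feature ranking.  Ties in either ranking are broken by
#' stable input order.
#'
#' @param distance distance feature per patient.
#' @param covariate clinical covariate per patient (e.g. SANS count,
#'   hospitalizations, dose load).
#' @param top_k how many top-covariate patients to check.
#' @return list: `count` (0..top_k), `top_subjects` (indices),
#'   `severe_half` (indices).
#' @export
severe_half_check <- function(distance, covariate, top_k = 5) {
  n <- length(distance)
  if (length(covariate) != n)
    stop_config("severe_half_check: lengths differ")
  if (n < 2 * top_k)
    stop_config("severe_half_check: need >= %d patients", 2 * top_k)
  top <- order(-covariate)[seq_len(top_k)]          # stable ties
  severe <- order(-distance)[seq_len(ceiling(n / 2))]
  list(count = sum(top %in% severe), top_subjects = top,
       severe_half = severe)
}
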