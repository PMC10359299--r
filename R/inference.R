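#' Empirical null distribution container
#'
#' @param values Statistic values under permutation.
#' @param statistic Statistic name.
#' @param seed Seed that produced the permutations.
#' @return A `null_distribution`.
#' @export
null_distribution <- function(values, statistic = "statistic", seed = NA_integer_) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("null distribution must be non-empty and finite")
  structure(list(values = values, n_perm = length(values),
                 statistic = statistic, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.05, 0.5, 0.95))
  cat("Null distribution of", x$statistic, "(", x$n_perm, "permutations )\n")
  cat(sprintf("  5th / 50th / 95th percentile: %.3f / %.3f / %.3f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' @export
quantile.null_distribution <- function(x, probs = c(0.05, 0.95), ...) {
  stats::quantile(x$values, probs, ...)
}

#' Permutation null of group-mean decoding accuracy
#'
#' For each permutation, one shuffle of the block labels is drawn and
#' applied identically to every participant (a fixed permutation order
#' across participants), each participant is re-decoded with
#' leave-two-blocks-out cross-validation, and the group-mean accuracy is
#' stored. The observed (unshuffled) statistic is never added to the null.
#'
#' @param pattern_sets List of per-subject `beta_patterns` sharing one block
#'   structure.
#' @param n_perm Number of permutations (default 1000).
#' @param cost SVM cost.
#' @param seed Integer seed.
#' @return A `null_distribution` of group-mean accuracy (%).
#' @export
null_decoding <- function(pattern_sets, n_perm = 1000, cost = 1, seed = 1L) {
  labs <- pattern_sets[[1]]$labels$inference
  for (p in pattern_sets)
    if (!identical(p$labels$inference, labs))
      stop("subjects differ in block structure")
  grams <- lapply(pattern_sets, function(p) tcrossprod(p$patterns))
  set.seed(seed)
  nb <- length(labs)
  vals <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(nb)
    pl <- labs[perm]
    y <- inference_y(pl)
    folds <- leave_two_blocks_out_folds(pl)
    mean(vapply(grams, function(K) .svc_cv_accuracy_gram(K, y, folds, cost), 0))
  }, 0)
  null_distribution(vals, "group-mean decoding accuracy", seed)
}

#' Permutation null of the cross-validated prediction accuracy r
#'
#' Shuffles the pairing of subjects' feature rows and scores and re-runs the
#' full leave-one-participant-out nu-SVR pipeline per permutation, storing
#' the accuracy r. The observed statistic is not included in the null set.
#'
#' @param features Subjects-by-voxels matrix or [feature_matrix()].
#' @param scores Behavioral scores.
#' @param n_perm Number of permutations (default 1000).
#' @param nu,cost SVR parameters.
#' @param standardize z-score labels within sample (default TRUE).
#' @param seed Integer seed.
#' @return A `null_distribution` of r.
#' @export
null_svr <- function(features, scores, n_perm = 1000, nu = 0.5, cost = 1,
                     standardize = TRUE, seed = 1L) {
  X <- if (inherits(features, "feature_matrix")) features$X else
    as.matrix(features)
  y <- if (standardize) as.numeric(scale(scores)) else as.numeric(scores)
  K <- tcrossprod(X)
  n <- nrow(X)
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(i) {
    yp <- y[sample.int(n)]
    pred <- .loo_svr_gram(K, yp, cost, nu)
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, yp)
  }, 0)
  null_distribution(vals, "prediction accuracy r", seed)
}

#' Permutation p-value and 95th-percentile significance
#'
#' One-sided add-one p-value, `p = (1 + #\{null >= observed\}) / (n_perm + 1)`
#' (never exactly zero), together with the decision rule used for all
#' permutation tests: significant iff the observed statistic lies strictly
#' above the null's 95th percentile.
#'
#' @param observed Observed statistic (finite scalar).
#' @param null A [null_distribution()].
#' @param percentile Significance percentile (default 95).
#' @return List with `p`, `significant`, `cutoff`, `null_q05`, `null_q95`.
#' @export
perm_pvalue <- function(observed, null, percentile = 95) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.finite(observed)) stop("observed statistic must be finite")
  v <- null$values
  p <- (1 + sum(v >= observed)) / (null$n_perm + 1)
  cutoff <- as.numeric(stats::quantile(v, percentile / 100))
  list(p = p, significant = observed > cutoff, cutoff = cutoff,
       null_q05 = as.numeric(stats::quantile(v, 0.05)),
       null_q95 = as.numeric(stats::quantile(v, 0.95)))
}

#' Attach a permutation test to a prediction result
#'
#' Convenience wrapper: builds the label-shuffle null for a fitted
#' [lopo_svr()] result and stores p, significance and null percentiles on
#' the object.
#'
#' @param result A `prediction_result` from [lopo_svr()].
#' @param features,scores The inputs the result was fitted on.
#' @param n_perm,seed Null construction parameters.
#' @export
test_prediction <- function(result, features, scores, n_perm = 1000,
                            seed = 1L) {
  null <- null_svr(features, scores, n_perm = n_perm, nu = result$nu,
                   cost = result$cost, seed = seed)
  pv <- perm_pvalue(result$r, null)
  result$p <- pv$p
  result$significant <- pv$significant
  result$null_q05 <- pv$null_q05
  result$null_q95 <- pv$null_q95
  result$n_perm <- n_perm
  result
}

#' False discovery rate correction across a test family
#'
#' Benjamini-Hochberg step-up (default) or Benjamini-Yekutieli across the
#' family of ROI-wise tests; returns the rejection set and monotone
#' adjusted p-values.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return List with `rejected` (logical) and `p_adjusted`.
#' @export
fdr_correct <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  list(rejected = adj <= q, p_adjusted = adj)
}

#' Two-sample comparison of accuracies or scores
#'
#' Pooled-variance (default) or Welch two-sample t-test, two-tailed, with a
#' confidence interval on the group difference.
#'
#' @param a,b Numeric vectors for the two groups (each n >= 2).
#' @param pooled Use the pooled-variance test (default TRUE).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `t`, `df`, `p`, `ci`, `estimate`.
#' @export
group_compare <- function(a, b, pooled = TRUE, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  ht <- stats::t.test(a, b, var.equal = pooled, conf.level = conf_level)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, ci = unname(ht$conf.int),
       estimate = unname(diff(rev(ht$estimate))))
}
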