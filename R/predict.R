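#' Subjects-by-voxels feature matrix from contrast images
#'
#' Extracts each subject's contrast values within one ROI and stacks them as
#' rows of a feature matrix for score prediction.
#'
#' @param contrasts Subjects-by-voxels matrix of contrast images (full
#'   grid or in-mask columns), or a list of per-subject contrast vectors.
#' @param roi Voxel indices (into the columns of `contrasts`) of the ROI.
#' @param sample Optional per-subject sample labels.
#' @return A `feature_matrix`: `$X`, `$sample`, `$roi`.
#' @export
feature_matrix <- function(contrasts, roi, sample = NULL) {
  if (is.list(contrasts) && !is.matrix(contrasts))
    contrasts <- do.call(rbind, contrasts)
  X <- contrasts[, roi, drop = FALSE]
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (nrow(X) < 3) stop("need >= 3 subjects")
  structure(list(X = unname(X),
                 sample = sample %||% rep("A", nrow(X)),
                 roi = roi), class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction accuracy: Pearson r and R-squared
#'
#' The prediction accuracy convention used throughout: the Pearson
#' correlation of predicted and observed scores across subjects, with
#' `R^2 = r^2` exactly.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 3), neither
#'   constant.
#' @return Named vector `c(r, r_squared)`.
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 3)
    stop("predicted and observed must have equal length >= 3")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(predicted, observed)
  c(r = r, r_squared = r^2)
}

#' Leave-one-participant-out nu-SVR score prediction
#'
#' For each subject, trains a linear nu-support-vector regression (fixed
#' cost, default `c = 1`) on the remaining subjects' ROI pattern vectors and
#' z-scored scores, and predicts the held-out subject. The accuracy is the
#' Pearson correlation of predicted and observed scores across all subjects.
#'
#' @param features A [feature_matrix()] or subjects-by-voxels matrix.
#' @param scores Behavioral scores (z-scored within the sample unless
#'   `standardize = FALSE` and they already are).
#' @param nu nu parameter of the SVR (default 0.5).
#' @param cost Cost parameter (default 1).
#' @param standardize z-score the labels within the sample (default TRUE).
#' @return A `prediction_result`: per-subject `$predicted` and `$observed`
#'   (z units), `$r`, `$r_squared`, `$n_folds`.
#' @export
lopo_svr <- function(features, scores, nu = 0.5, cost = 1,
                     standardize = TRUE) {
  X <- if (inherits(features, "feature_matrix")) features$X else
    as.matrix(features)
  if (anyNA(X)) stop("features contain missing values")
  n <- nrow(X)
  if (n < 3) stop("need >= 3 subjects")
  if (length(scores) != n) stop("scores must match feature rows")
  if (stats::sd(scores) == 0) stop("labels are constant; correlation undefined")
  y <- if (standardize) as.numeric(scale(scores)) else as.numeric(scores)
  K <- tcrossprod(X)
  pred <- .loo_svr_gram(K, y, cost, nu)
  acc <- prediction_accuracy(pred, y)
  structure(list(predicted = pred, observed = y, r = unname(acc["r"]),
                 r_squared = unname(acc["r_squared"]), n_folds = n,
                 nu = nu, cost = cost, scheme = "lopo"),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("Cross-validated score prediction (", x$scheme, ", ", x$n_folds,
      " folds)\n", sep = "")
  cat(sprintf("  accuracy r = %.3f, R^2 = %.3f\n", x$r, x$r_squared))
  if (!is.null(x$p)) {
    cat(sprintf("  permutation p = %.4g (null 5th/95th: %.3f / %.3f)%s\n",
                x$p, x$null_q05, x$null_q95,
                if (isTRUE(x$significant)) " *" else ""))
  }
  invisible(x)
}

#' @export
plot.prediction_result <- function(x, ...) {
  plot(x$observed, x$predicted, xlab = "observed score (z)",
       ylab = "predicted score (z)",
       main = sprintf("r = %.2f, R2 = %.2f", x$r, x$r_squared), ...)
  graphics::abline(stats::lm(x$predicted ~ x$observed), lty = 2)
  invisible(x)
}

#' Cross-sample nu-SVR score prediction
#'
#' Trains one linear nu-SVR on the pooled rows of several training samples
#' and tests on a held-out sample. Features (each voxel column) and labels
#' are standardized within each sample separately before pooling, so
#' between-sample scanner and scale differences do not drive the fit.
#'
#' @param train_features Subjects-by-voxels matrix for the training pool.
#' @param train_scores Training scores.
#' @param train_sample Factor of sample membership for the training rows
#'   (>= 2 distinct samples).
#' @param test_features,test_scores Held-out sample (same voxel columns).
#' @param nu,cost SVR parameters.
#' @return A `prediction_result` with `$scheme = "cross_sample"`.
#' @export
cross_sample_svr <- function(train_features, train_scores, train_sample,
                             test_features, test_scores, nu = 0.5, cost = 1) {
  Xtr <- as.matrix(train_features); Xte <- as.matrix(test_features)
  if (ncol(Xtr) != ncol(Xte))
    stop("train and test voxel lists differ; features are not aligned")
  train_sample <- as.factor(train_sample)
  if (nlevels(train_sample) < 2) stop("need >= 2 training samples")
  zcols <- function(M) {
    mu <- colMeans(M); sg <- apply(M, 2, stats::sd); sg[sg == 0] <- 1
    sweep(sweep(M, 2, mu), 2, sg, "/")
  }
  for (lv in levels(train_sample)) {
    i <- train_sample == lv
    Xtr[i, ] <- zcols(Xtr[i, , drop = FALSE])
    train_scores[i] <- as.numeric(scale(train_scores[i]))
  }
  Xte <- zcols(Xte)
  yte <- as.numeric(scale(test_scores))
  K <- tcrossprod(Xtr)
  m <- .nusvr_fit_gram(K, train_scores, cost, nu)
  pred <- as.vector(Xte %*% crossprod(Xtr, m$beta)) + m$b
  acc <- prediction_accuracy(pred, yte)
  structure(list(predicted = pred, observed = yte, r = unname(acc["r"]),
                 r_squared = unname(acc["r_squared"]),
                 n_folds = 1L, n_train = nrow(Xtr), nu = nu, cost = cost,
                 scheme = "cross_sample"), class = "prediction_result")
}

#' Univariate ROI-mean association with a score
#'
#' Control analysis: correlates each subject's mean contrast value within an
#' ROI with the behavioral score (Pearson, two-tailed t-approximation p).
#' A score carried purely by pattern orientation (zero mean shift) yields a
#' null result here while the multivariate prediction succeeds.
#'
#' @param contrasts Subjects-by-voxels contrast matrix.
#' @param roi Voxel indices of the ROI.
#' @param scores Behavioral scores.
#' @return Named vector `c(r, p)`.
#' @export
roi_mean_univariate_assoc <- function(contrasts, roi, scores) {
  if (!length(roi)) stop("empty ROI")
  m <- rowMeans(as.matrix(contrasts)[, roi, drop = FALSE])
  if (length(m) < 3) stop("need >= 3 subjects")
  if (stats::sd(m) == 0) stop("constant ROI means; correlation undefined")
  ct <- stats::cor.test(m, scores)
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation of per-subject decoding accuracies with scores
#'
#' @param accuracies Per-subject ROI decoding accuracies (%).
#' @param scores Behavioral scores.
#' @return Named vector `c(r, p)` (Pearson, two-tailed).
#' @export
accuracy_score_correlation <- function(accuracies, scores) {
  if (length(accuracies) < 3) stop("need >= 3 subjects")
  if (stats::sd(accuracies) == 0)
    stop("constant accuracies; correlation undefined")
  ct <- stats::cor.test(accuracies, scores)
  c(r = unname(ct$estimate), p = ct$p.value)
}
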