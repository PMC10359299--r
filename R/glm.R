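#' Fit the block-wise GLM with robust weighted least squares
#'
#' Estimates per-voxel coefficients for every design-matrix column. The
#' robust variant iteratively reweights timepoints by the inverse of their
#' residual variance (estimated by pooling squared residuals across voxels),
#' which downweights artifact-laden frames; plain OLS is available behind
#' `method = "ols"`.
#'
#' @param series Voxels-by-time matrix (or a `subject_data` object).
#' @param dm A [build_design_matrix()] object.
#' @param method `"rwls"` (default) or `"ols"`.
#' @param max_iter Reweighting iterations for `"rwls"` (default 2).
#' @param tol Stop when the maximum absolute weight change drops below this.
#' @return A `glm_fit`: `$betas` (regressors x voxels), `$weights`
#'   (per-timepoint), `$labels`, `$block_info`, residual variance `$sigma2`.
#' @export
fit_glm <- function(series, dm, method = c("rwls", "ols"), max_iter = 2,
                    tol = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "design_matrix"))
  if (inherits(series, "subject_data")) series <- series$series
  X <- dm$X
  n <- nrow(X)
  if (ncol(series) != n)
    stop("series has ", ncol(series), " volumes but design has ", n)
  if (n <= ncol(X)) stop("need more volumes than regressors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(series)                       # time x voxels
  w <- rep(1, n)
  fit_wls <- function(w) {
    sw <- sqrt(w)
    qr.coef(qr(X * sw), Y * sw)
  }
  B <- fit_wls(w)
  if (method == "rwls") {
    for (it in seq_len(max_iter)) {
      E <- Y - X %*% B
      s2 <- rowMeans(E^2)              # per-timepoint variance, pooled over voxels
      s2 <- pmax(s2, 1e-12)
      w_new <- (1 / s2) / mean(1 / s2)
      delta <- max(abs(w_new - w))
      w <- w_new
      B <- fit_wls(w)
      if (delta < tol) break
    }
  }
  E <- Y - X %*% B
  structure(list(betas = B, weights = w, labels = colnames(X),
                 task_cols = dm$task_cols, block_info = dm$block_info,
                 sigma2 = colSums(E^2 * w) / (n - ncol(X)),
                 method = method), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit (", x$method, "):", length(x$labels), "regressors x",
      ncol(x$betas), "voxels\n")
  invisible(x)
}

#' Extract labelled block-wise pattern vectors from a GLM fit
#'
#' Returns the per-block beta estimates as a pattern set: one multivoxel
#' vector per task block, labelled by inference (why/how) and target
#' condition — the unit of analysis for all decoding.
#'
#' @param fit A [fit_glm()] object.
#' @param targets Restrict to these target conditions (default all).
#' @param voxels Optional voxel index subset (e.g. an ROI).
#' @return A `beta_patterns` object: `$patterns` (blocks x voxels),
#'   `$labels` (block/inference/target), `$voxels`.
#' @export
block_patterns <- function(fit, targets = NULL, voxels = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  info <- fit$block_info
  keep <- if (is.null(targets)) seq_len(nrow(info)) else
    which(info$target %in% targets)
  if (!length(keep)) stop("no blocks for requested targets")
  P <- fit$betas[info$block[keep], , drop = FALSE]
  if (!is.null(voxels)) P <- P[, voxels, drop = FALSE]
  structure(list(patterns = unname(P), labels = info[keep, , drop = FALSE],
                 voxels = if (is.null(voxels)) seq_len(ncol(P)) else voxels),
            class = "beta_patterns")
}

#' Compute a contrast image from block-wise betas
#'
#' The social contrast averages all why-face and why-hand block betas and
#' subtracts the average of all how-face and how-hand block betas; the
#' nonsocial contrast does the same on nonsocial blocks only. Arbitrary named
#' weight vectors over block regressors are also accepted (difference
#' contrasts must have weights summing to zero).
#'
#' @param fit A [fit_glm()] object.
#' @param contrast `"social"`, `"nonsocial"`, or a named numeric vector of
#'   weights over block regressor labels.
#' @return Named numeric vector of per-voxel contrast values with attribute
#'   `"contrast"`.
#' @export
contrast_image <- function(fit, contrast = "social") {
  stopifnot(inherits(fit, "glm_fit"))
  info <- fit$block_info
  if (is.character(contrast) && length(contrast) == 1) {
    tg <- if (contrast == "social") c("faces", "hands") else
      if (contrast == "nonsocial") "nonsocial" else
        stop("unknown named contrast: ", contrast)
    if (!any(info$target %in% tg))
      stop("condition unavailable: no ", paste(tg, collapse = "/"),
           " blocks in this design")
    why <- info$block[info$inference == "why" & info$target %in% tg]
    how <- info$block[info$inference == "how" & info$target %in% tg]
    w <- c(stats::setNames(rep(1 / length(why), length(why)), why),
           stats::setNames(rep(-1 / length(how), length(how)), how))
    cname <- contrast
  } else {
    w <- contrast
    if (is.null(names(w)) || !all(names(w) %in% info$block))
      stop("contrast weights must be named by block regressors")
    if (abs(sum(w)) > 1e-8 && any(w < 0))
      stop("difference contrast weights must sum to zero")
    cname <- "custom"
  }
  img <- as.vector(t(w) %*% fit$betas[names(w), , drop = FALSE])
  attr(img, "contrast") <- cname
  img
}
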