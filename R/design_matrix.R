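#' Build the GLM design matrix for a block design
#'
#' One boxcar regressor per task block (spanning the onset of the block's
#' first target image to the offset of its final image), convolved with the
#' canonical double-gamma HRF and sampled at the TR. Low-frequency drift is
#' modelled as a discrete-cosine basis up to the high-pass cutoff (the
#' filtering stays inside a single least-squares problem); motion traces and
#' single-frame spike indicators are appended as nuisance columns, plus an
#' intercept.
#'
#' @param design A [make_block_design()] object.
#' @param hrf_params Optional list of [canonical_hrf()] parameters.
#' @param highpass_cutoff High-pass cutoff period in seconds (default 100,
#'   i.e. a 1/100 Hz cutoff); `NULL` drops the drift basis.
#' @param motion Optional `n_volumes x 6` matrix of rigid-body parameters.
#' @param spike_frames Integer frame indices to receive unit spike regressors.
#' @return A `design_matrix`: `$X` with labelled columns, `$task_cols`,
#'   `$block_info` (inference/target per task column), `$tr`.
#' @export
build_design_matrix <- function(design, hrf_params = list(),
                                highpass_cutoff = 100, motion = NULL,
                                spike_frames = integer(0)) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_volumes
  scan_end <- n * design$tr
  b <- design$blocks
  if (any(b$offset > scan_end)) stop("block outside scan")
  task <- task_regressors(design, hrf_params)
  if (any(colSums(abs(task)) == 0)) stop("all-zero task regressor")

  X <- task
  if (!is.null(highpass_cutoff)) {
    k <- floor(2 * scan_end / highpass_cutoff)
    if (k >= 1) {
      i <- seq_len(n) - 1
      drift <- vapply(seq_len(k), function(j)
        cos(pi * j * (2 * i + 1) / (2 * n)), numeric(n))
      colnames(drift) <- paste0("drift", seq_len(k))
      X <- cbind(X, drift)
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n || ncol(motion) != 6)
      stop("motion must be n_volumes x 6")
    mc <- scale(motion, scale = FALSE)
    colnames(mc) <- paste0("motion", 1:6)
    X <- cbind(X, mc)
  }
  spike_frames <- sort(unique(as.integer(spike_frames)))
  if (length(spike_frames)) {
    if (any(spike_frames < 1 | spike_frames > n))
      stop("spike frames outside scan")
    sp <- matrix(0, n, length(spike_frames),
                 dimnames = list(NULL, paste0("spike", spike_frames)))
    sp[cbind(spike_frames, seq_along(spike_frames))] <- 1
    X <- cbind(X, sp)
  }
  X <- cbind(X, intercept = 1)
  if (anyDuplicated(colnames(X))) stop("duplicate design-matrix columns")
  structure(list(X = X, task_cols = colnames(task),
                 block_info = b[, c("block", "condition", "inference", "target")],
                 tr = design$tr), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "volumes x", ncol(x$X), "regressors (",
      length(x$task_cols), "task blocks )\n")
  invisible(x)
}
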