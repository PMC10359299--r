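#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, the conventional "canonical" HRF: a
#' positive response peaking a few seconds after stimulus onset and a late
#' undershoot, normalized to unit peak amplitude.
#'
#' @param t Time in seconds (vector, all `>= 0`).
#' @param delay Delay of the response gamma (seconds; shape = delay/dispersion).
#' @param undershoot Delay of the undershoot gamma (seconds).
#' @param dispersion,u_dispersion Dispersions of response and undershoot.
#' @param ratio Relative amplitude of the undershoot (response:undershoot).
#' @return Amplitude at `t` (arbitrary units, unit peak).
#' @examples
#' tt <- seq(0, 32, by = 0.1)
#' h <- canonical_hrf(tt)
#' tt[which.max(h)]  # peaks near 5 s with the defaults
#' @export
canonical_hrf <- function(t, delay = 6, undershoot = 16, dispersion = 1,
                          u_dispersion = 1, ratio = 1 / 6) {
  if (delay <= 0 || undershoot <= 0 || dispersion <= 0 || u_dispersion <= 0 ||
      ratio < 0)
    stop("HRF shape parameters must be positive")
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative")
  raw <- function(x)
    dgamma(x, shape = delay / dispersion, rate = 1 / dispersion) -
      ratio * dgamma(x, shape = undershoot / u_dispersion, rate = 1 / u_dispersion)
  peak <- max(raw(seq(0, delay + 4 * dispersion, by = 0.01)))
  raw(t) / peak
}

# sample one HRF-convolved boxcar regressor at the frame times
# (oversampled discrete convolution on a dt grid)
convolve_boxcar <- function(onset, offset, n_volumes, tr, hrf_params = list(),
                            dt = 0.1) {
  t_hi <- seq(0, n_volumes * tr, by = dt)
  box <- as.numeric(t_hi >= onset & t_hi < offset)
  h <- do.call(canonical_hrf, c(list(t = seq(0, 32, by = dt)), hrf_params))
  reg <- stats::convolve(box, rev(h), type = "open")[seq_along(t_hi)] * dt
  frame_t <- (seq_len(n_volumes) - 1) * tr
  reg[round(frame_t / dt) + 1]
}

# HRF-convolved regressor matrix (n_volumes x n_blocks) for a design;
# memoized because the block timeline is identical across subjects
.regressor_cache <- new.env(parent = emptyenv())

task_regressors <- function(design, hrf_params = list()) {
  b <- design$blocks
  key <- paste(c(format(b$onset, digits = 12), format(b$offset, digits = 12),
                 design$tr, design$n_volumes,
                 unlist(hrf_params, use.names = TRUE)), collapse = "|")
  hit <- .regressor_cache[[key]]
  if (!is.null(hit)) return(hit)
  reg <- vapply(seq_len(nrow(b)), function(i)
    convolve_boxcar(b$onset[i], b$offset[i], design$n_volumes, design$tr,
                    hrf_params), numeric(design$n_volumes))
  colnames(reg) <- b$block
  if (length(ls(.regressor_cache)) > 20) # bounded cache
    rm(list = ls(.regressor_cache), envir = .regressor_cache)
  .regressor_cache[[key]] <- reg
  reg
}
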