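#' Define the generative ground truth for a simulated study
#'
#' Fixes the voxel grid, the planted effect regions, and the generative
#' gains that downstream stages try to recover: a multivoxel why-vs-how
#' condition pattern per region (partially shared across subjects), and a
#' linear encoding of one behavioral score in the why-minus-how contrast
#' pattern of a designated region. Group-level patterns are drawn once here
#' from the truth seed, so an identical truth object reproduces identical
#' studies.
#'
#' @param dim Grid dimensions in voxels, length 3.
#' @param voxel_size Isotropic voxel size in mm.
#' @param regions Named list of voxel index vectors (linear indices into the
#'   grid); see [region_box()].
#' @param condition_effect_gain Amplitude of the why-vs-how pattern, one
#'   value recycled over regions or a named vector (arbitrary signal units).
#' @param shared_fraction Proportion of the condition pattern common across
#'   subjects, in `[0, 1]`.
#' @param score_encoding_gain Contrast-pattern amplitude per unit z-score of
#'   the encoded behavioral measure.
#' @param encoding_region Name of the region carrying the score encoding.
#' @param encoding_targets Target conditions whose why-minus-how modulation
#'   carries the encoding (default the social targets, faces and hands, so
#'   nonsocial-contrast features stay uninformative about the score).
#' @param noise_sd Gaussian noise SD (signal units; baseline is 100).
#' @param drift_sd SD of random low-order polynomial drift (0 disables).
#' @param ar1 Lag-1 autocorrelation of the noise (0 = white).
#' @param spike_prob Per-frame probability of a step displacement in the
#'   motion trace.
#' @param spike_magnitude Translation step size of motion spikes (mm).
#' @param seed Integer seed for the group-level patterns.
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(dim = c(20, 20, 20), voxel_size = 3,
                              regions = list(), condition_effect_gain = 0.3,
                              shared_fraction = 0.5, score_encoding_gain = 0,
                              encoding_region = if (length(regions)) names(regions)[1] else NULL,
                              encoding_targets = c("faces", "hands"),
                              noise_sd = 1, drift_sd = 0, ar1 = 0,
                              spike_prob = 0, spike_magnitude = 1,
                              seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 1))
  nvox <- prod(dim)
  if (length(regions)) {
    if (is.null(names(regions)) || anyDuplicated(names(regions)))
      stop("regions must have unique names")
    for (r in regions)
      if (any(r < 1 | r > nvox)) stop("planted region outside grid")
  }
  if (any(condition_effect_gain < 0) || score_encoding_gain < 0)
    stop("gains must be >= 0")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  gains <- if (length(condition_effect_gain) == 1)
    stats::setNames(rep(condition_effect_gain, length(regions)), names(regions))
  else condition_effect_gain[names(regions)]

  # group-level patterns, fixed by the truth seed
  set.seed(seed)
  unitize <- function(v) if (sum(v^2) > 0) v / sqrt(sum(v^2)) else v
  group_patterns <- lapply(regions, function(r) unitize(stats::rnorm(length(r))))
  encoding_pattern <- NULL
  if (!is.null(encoding_region)) {
    if (!encoding_region %in% names(regions))
      stop("encoding_region must name a planted region")
    q <- stats::rnorm(length(regions[[encoding_region]]))
    encoding_pattern <- unitize(q - mean(q))  # zero-mean: pure pattern code
  }
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 regions = regions, gains = gains,
                 shared_fraction = shared_fraction,
                 score_encoding_gain = score_encoding_gain,
                 encoding_region = encoding_region,
                 encoding_targets = encoding_targets,
                 group_patterns = group_patterns,
                 encoding_pattern = encoding_pattern,
                 noise_sd = noise_sd, drift_sd = drift_sd, ar1 = ar1,
                 spike_prob = spike_prob, spike_magnitude = spike_magnitude,
                 seed = as.integer(seed)), class = "ground_truth")
}

#' Rectangular region of voxels on a grid
#'
#' Convenience constructor of linear voxel indices for a box
#' `center +/- half` in each dimension, clipped to the grid.
#' @param dim Grid dimensions (length 3).
#' @param center Box center in voxel coordinates (1-based).
#' @param half Half-widths per dimension (scalar or length 3).
#' @export
region_box <- function(dim, center, half) {
  half <- rep(half, length.out = 3)
  rng <- lapply(1:3, function(a)
    max(1, center[a] - half[a]):min(dim[a], center[a] + half[a]))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  sort(g[, 1] + (g[, 2] - 1) * dim[1] + (g[, 3] - 1) * dim[1] * dim[2])
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", paste(x$dim, collapse = "x"), "grid,",
      length(x$regions), "planted regions\n")
  cat("  condition gain:", paste(signif(x$gains, 3), collapse = ", "),
      "; shared fraction:", x$shared_fraction,
      "; score encoding gain:", x$score_encoding_gain, "\n")
  cat("  noise sd:", x$noise_sd, "; drift sd:", x$drift_sd,
      "; AR(1):", x$ar1, "\n")
  invisible(x)
}
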