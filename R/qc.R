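#' Zero-phase Butterworth low-pass filter
#'
#' Fifth-order (by default) Butterworth low-pass applied forward and
#' backward (zero phase, squared magnitude response), used to remove
#' respiration and pseudo-motion content from rigid-body motion traces
#' before computing framewise displacement. DC gain is 1.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param order Filter order (default 5).
#' @param cutoff_hz Critical frequency in Hz (default 0.2; must be below the
#'   Nyquist frequency).
#' @param sampling_hz Sampling rate in Hz (for fMRI motion, `1 / TR`).
#' @export
butterworth_lowpass <- function(x, order = 5, cutoff_hz = 0.2, sampling_hz) {
  if (cutoff_hz >= sampling_hz / 2)
    stop("cutoff must be below the Nyquist frequency (",
         sampling_hz / 2, " Hz)")
  nlen <- if (is.matrix(x)) nrow(x) else length(x)
  if (nlen <= 3 * order) stop("series too short for the requested order")
  bf <- signal::butter(order, cutoff_hz / (sampling_hz / 2), type = "low")
  f1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' `FD_t = sum |delta translation| + r * sum |delta rotation|`, the summed
#' absolute frame-to-frame differentials with rotations converted to arc
#' length on a sphere of radius `head_radius_mm`. The first frame is 0.
#'
#' @param motion `n x 6` matrix: 3 translations (mm) then 3 rotations (rad).
#' @param head_radius_mm Sphere radius for the rotation conversion (50 mm).
#' @return FD series in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' DVARS: RMS frame-to-frame signal change
#'
#' Root mean square, over in-mask voxels, of the temporal derivative of the
#' signal; the first frame is 0.
#'
#' @param series Voxels-by-time matrix (or `subject_data`).
#' @param mask Logical vector or voxel indices; `NULL` uses all voxels.
#' @export
dvars <- function(series, mask = NULL) {
  if (inherits(series, "subject_data")) series <- series$series
  if (!is.null(mask)) {
    series <- series[mask, , drop = FALSE]
    if (nrow(series) == 0) stop("empty mask")
  }
  if (nrow(series) == 0) stop("empty mask")
  d <- series[, -1, drop = FALSE] - series[, -ncol(series), drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' Identify spike frames for nuisance regression
#'
#' A frame is a spike when its translation differential exceeds
#' `fd_translation_mm`, its rotation differential exceeds `rotation_deg`, or
#' its DVARS exceeds the series mean by `dvars_sd` standard deviations.
#' Translation and rotation are thresholded separately (the combined FD is
#' used for participant-level exclusion, not spike flagging).
#'
#' @param motion `n x 6` motion matrix (rotations in radians).
#' @param series Optional voxels-by-time matrix for the DVARS criterion.
#' @param mask Optional mask for DVARS.
#' @param fd_translation_mm Translation threshold per frame (default 0.5).
#' @param rotation_deg Rotation threshold per frame in degrees (default 0.5).
#' @param dvars_sd DVARS threshold in SDs above the mean (default 2.5).
#' @return Sorted integer frame indices.
#' @export
spike_frames <- function(motion, series = NULL, mask = NULL,
                         fd_translation_mm = 0.5, rotation_deg = 0.5,
                         dvars_sd = 2.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  d <- abs(diff(motion))
  trans <- c(0, rowSums(d[, 1:3, drop = FALSE]))
  rot <- c(0, rowSums(d[, 4:6, drop = FALSE])) * 180 / pi
  bad <- trans > fd_translation_mm | rot > rotation_deg
  if (!is.null(series)) {
    v <- dvars(series, mask)
    bad <- bad | v > mean(v) + dvars_sd * stats::sd(v)
  }
  which(bad)
}

#' Per-subject motion quality-control report
#'
#' Low-pass filters the motion parameters (to suppress respiratory and
#' pseudo-motion content), computes framewise displacement, and reports its
#' 50th and 95th percentiles together with the spike frames.
#'
#' @param motion `n x 6` motion matrix.
#' @param tr Repetition time in seconds.
#' @param series Optional series for the DVARS spike criterion.
#' @param mask Optional DVARS mask.
#' @param filter_motion Apply the Butterworth low-pass before FD (default
#'   TRUE).
#' @param ... Passed to [spike_frames()].
#' @return A `motion_qc` list: `fd`, `fd_p50`, `fd_p95`, `spike_frames`.
#' @export
motion_qc <- function(motion, tr, series = NULL, mask = NULL,
                      filter_motion = TRUE, ...) {
  m <- as.matrix(motion)
  mf <- if (filter_motion && nrow(m) > 15)
    butterworth_lowpass(m, sampling_hz = 1 / tr) else m
  fd <- framewise_displacement(mf)
  structure(list(fd = fd,
                 fd_p50 = as.numeric(stats::quantile(fd, 0.5)),
                 fd_p95 = as.numeric(stats::quantile(fd, 0.95)),
                 spike_frames = spike_frames(m, series, mask, ...)),
            class = "motion_qc")
}

# plain density-based clustering (DBSCAN); labels: 0 = noise, 1.. = clusters
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in neighbors[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Flag motion-outlier participants by density clustering
#'
#' Runs density-based clustering (DBSCAN) on the 2-D per-subject points
#' (FD 50th percentile, FD 95th percentile); subjects falling outside the
#' largest cluster are flagged as motion outliers. By default `eps` is
#' `eps_mult` times the median nearest-neighbor distance (5 by default:
#' tighter data-driven radii leave too few core points at cohort sizes of
#' 10-60 and flag much of a well-behaved sample) and `min_pts = 4`.
#'
#' @param fd_stats Data frame or matrix with columns `fd_p50` and `fd_p95`
#'   (one row per subject), or a list of [motion_qc()] objects.
#' @param eps Neighborhood radius (default from the data as above).
#' @param eps_mult Multiplier on the median nearest-neighbor distance used
#'   when `eps` is not given.
#' @param min_pts Minimum neighborhood size for a core point.
#' @return Logical outlier flag per subject.
#' @export
flag_outlier_participants <- function(fd_stats, eps = NULL, eps_mult = 5,
                                      min_pts = 4) {
  if (is.list(fd_stats) && !is.data.frame(fd_stats) &&
      all(vapply(fd_stats, inherits, TRUE, "motion_qc")))
    fd_stats <- data.frame(fd_p50 = vapply(fd_stats, `[[`, 0, "fd_p50"),
                           fd_p95 = vapply(fd_stats, `[[`, 0, "fd_p95"))
  X <- as.matrix(fd_stats[, c("fd_p50", "fd_p95")])
  n <- nrow(X)
  if (n < 5) stop("too few subjects (< 5) for density-based outlier flagging")
  if (is.null(eps)) {
    D <- as.matrix(stats::dist(X)); diag(D) <- Inf
    nn <- apply(D, 1, min)
    eps <- eps_mult * stats::median(nn)
  }
  labels <- dbscan_labels(X, eps, min_pts)
  if (all(labels == 0L)) return(rep(TRUE, n))
  main <- as.integer(names(which.max(table(labels[labels > 0L]))))
  labels != main
}
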