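#' Write a volume (3-D or 4-D array) as NIfTI
#'
#' @param x Numeric array (3-D mask/map or 4-D series), or an
#'   `accuracy_map` (converted with [map_array()], `NA` outside the mask).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm.
#' @export
write_volume <- function(x, path, voxel_size = 3) {
  if (inherits(x, "accuracy_map")) x <- map_array(x)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(voxel_size, min(3, length(dim(x))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path File path.
#' @return Numeric array with attribute `"voxel_size"`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1]
  out
}

#' Check that two volumes share a grid
#'
#' Errors (printing both geometries) when dimensions or voxel sizes differ;
#' used before masking a series.
#' @param a,b Arrays from [read_volume()] (3-D mask may be checked against
#'   the spatial dimensions of a 4-D series).
#' @export
check_alignment <- function(a, b) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  va <- attr(a, "voxel_size") %||% NA; vb <- attr(b, "voxel_size") %||% NA
  if (!identical(da, db) || (is.finite(va) && is.finite(vb) &&
                             abs(va - vb) > 1e-6))
    stop(sprintf(
      "volume grids are not aligned: %s @ %s mm vs %s @ %s mm",
      paste(da, collapse = "x"), format(va),
      paste(db, collapse = "x"), format(vb)))
  invisible(TRUE)
}

#' Write a block design as a BIDS-style events table
#'
#' One row per trial: `onset`, `duration` (the response window),
#' `trial_type` (condition), `response_time` (`n/a` when absent).
#'
#' @param design A `block_design`.
#' @param path Output TSV path.
#' @param response_times Optional per-trial RTs (seconds).
#' @export
write_events_tsv <- function(design, path, response_times = NULL) {
  tr <- design$trials
  rt <- response_times %||% rep(NA_real_, nrow(tr))
  df <- data.frame(onset = tr$onset, duration = tr$response_window,
                   trial_type = tr$condition,
                   response_time = ifelse(is.na(rt), "n/a", rt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' @param path TSV path with `onset`, `duration`, `trial_type` columns.
#' @return Data frame; `response_time` parsed with `n/a` as `NA`.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events file needs columns: ", paste(need, collapse = ", "))
  if ("response_time" %in% names(df))
    df$response_time <- suppressWarnings(as.numeric(df$response_time))
  df
}

#' Reconstruct block structure from an events table
#'
#' Groups consecutive same-condition trials into blocks (a new block starts
#' whenever the condition changes or the gap to the previous trial exceeds
#' `max_gap`).
#'
#' @param events Data frame from [read_events_tsv()].
#' @param max_gap Largest within-block inter-trial gap in seconds.
#' @return Data frame of blocks: condition, onset, offset, n_trials.
#' @export
blocks_from_events <- function(events, max_gap = 5) {
  ev <- events[order(events$onset), ]
  new_block <- c(TRUE, ev$trial_type[-1] != ev$trial_type[-nrow(ev)] |
                   diff(ev$onset) > max_gap)
  id <- cumsum(new_block)
  out <- do.call(rbind, lapply(split(ev, id), function(d)
    data.frame(condition = d$trial_type[1], onset = d$onset[1],
               offset = max(d$onset + d$duration), n_trials = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Write / read a motion parameter table
#' @param motion `n x 6` matrix.
#' @param path TSV path.
#' @export
write_motion_tsv <- function(motion, path) {
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  if (ncol(m) != 6) stop("motion file must have 6 columns")
  m
}

#' Default analysis configuration
#'
#' All fixed constants of the pipeline in one structure: design variant,
#' GLM options (HRF parameters, 100 s high-pass, robust WLS), QC thresholds
#' (0.5 mm translation / 0.5 degree rotation spikes, 2.5-SD DVARS,
#' fifth-order 0.2 Hz Butterworth), decoding options (radius 4, cost 1,
#' cluster threshold 5), prediction options (nu 0.5, cost 1) and inference
#' options (1000 permutations, 95th percentile, q = 0.05).
#' @export
default_config <- function() {
  list(
    grid = list(dim = c(20L, 20L, 20L), voxel_size = 3),
    design = list(n_blocks_per_condition = 4L, stimuli_per_block = 8L,
                  tr = 1, targets = c("faces", "hands")),
    glm = list(highpass_cutoff = 100, robust = TRUE,
               hrf = list(delay = 6, undershoot = 16, dispersion = 1,
                          u_dispersion = 1, ratio = 1 / 6)),
    qc = list(fd_translation_mm = 0.5, rotation_deg = 0.5, dvars_sd = 2.5,
              butterworth_order = 5L, butterworth_cutoff_hz = 0.2,
              head_radius_mm = 50),
    decoding = list(radius = 4L, cost = 1, cluster_k = 5L, alpha = 0.05),
    prediction = list(nu = 0.5, cost = 1),
    inference = list(n_perm = 1000L, percentile = 95, q = 0.05),
    simulation = list(n_subjects = 12L, condition_effect_gain = 1,
                      shared_fraction = 0.5, score_encoding_gain = 0,
                      noise_sd = 1, drift_sd = 0, ar1 = 0,
                      spike_prob = 0, spike_magnitude = 1),
    seed = 1L
  )
}

#' Load, validate and merge a configuration
#'
#' Reads a YAML configuration, merges it over [default_config()], and
#' checks the schema invariants (positive thresholds, percentile in
#' (50, 100), valid FDR level).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg Configuration list.
#' @export
validate_config <- function(cfg) {
  stopifnot(
    length(cfg$grid$dim) == 3, all(cfg$grid$dim >= 1),
    cfg$design$tr > 0,
    cfg$qc$fd_translation_mm > 0, cfg$qc$rotation_deg > 0,
    cfg$qc$dvars_sd > 0, cfg$qc$butterworth_cutoff_hz > 0,
    cfg$decoding$radius >= 0, cfg$decoding$cost > 0,
    cfg$decoding$cluster_k >= 1,
    cfg$decoding$alpha > 0, cfg$decoding$alpha < 1,
    cfg$prediction$nu > 0, cfg$prediction$nu <= 1, cfg$prediction$cost > 0,
    cfg$inference$n_perm >= 1,
    cfg$inference$percentile > 50, cfg$inference$percentile < 100,
    cfg$inference$q > 0, cfg$inference$q < 1)
  invisible(cfg)
}

#' Save a configuration as YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Provenance record for a pipeline run
#'
#' Captures the configuration hash, seeds, package version, timestamps and
#' md5 digests of outputs so identical configurations and seeds can be
#' verified to yield identical artifacts.
#'
#' @param cfg Configuration list.
#' @param files Character vector of artifact paths to digest.
#' @export
run_record <- function(cfg, files = character(0)) {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tf)
  on.exit(unlink(tf))
  files <- files[file.exists(files)]
  list(config_hash = unname(tools::md5sum(tf)),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("blockmvpa")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       file_digests = as.list(tools::md5sum(files)))
}
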