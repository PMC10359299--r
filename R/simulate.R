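#' Simulate one subject's block-design BOLD series
#'
#' Forward model: HRF-convolved block regressors scale a baseline of 100
#' plus, inside each planted region, a why-vs-how multivoxel pattern
#' (`+gain/2` for why blocks, `-gain/2` for how blocks). The per-subject
#' pattern mixes the group pattern with a subject-specific one according to
#' `shared_fraction` and is re-normalized to unit length. If a score
#' encoding is configured, `score_encoding_gain * score_z` additionally
#' scales a zero-mean encoding pattern in the designated region, riding on
#' the why-minus-how modulation of the encoding target conditions (the
#' social blocks by default, so nonsocial contrasts carry no score
#' information). Gaussian noise (optionally AR(1)),
#' optional polynomial drift, and a motion trace with occasional step
#' spikes complete the series. Identical seeds give bit-identical output.
#'
#' @param design A [make_block_design()] object.
#' @param truth A [make_ground_truth()] object.
#' @param score_z z-scored behavioral score of the encoded measure for this
#'   subject (0 when no encoding is wanted).
#' @param behavior Optional one-row behavior data frame carried along.
#' @param seed Integer seed for this subject.
#' @return A `subject_data` object: `$series` (voxels x volumes matrix with
#'   the grid in `$dim`), `$motion` (volumes x 6), `$behavior`, `$seed`.
#' @export
simulate_subject <- function(design, truth, score_z = 0, behavior = NULL,
                             seed = 1L) {
  stopifnot(inherits(design, "block_design"), inherits(truth, "ground_truth"))
  if (truth$score_encoding_gain > 0 && is.null(truth$encoding_pattern))
    stop("score encoding requested but truth has no encoding region")
  nvox <- prod(truth$dim)
  n <- design$n_volumes
  set.seed(seed)

  reg <- task_regressors(design)
  sign_b <- ifelse(design$blocks$inference == "why", 0.5, -0.5)
  task_mod <- as.vector(reg %*% sign_b)          # why-minus-how modulation
  enc_b <- sign_b * (design$blocks$target %in% truth$encoding_targets)
  enc_mod <- as.vector(reg %*% enc_b)            # social-only modulation
  block_drive <- rowSums(reg)                    # common task response

  series <- matrix(stats::rnorm(nvox * n, sd = truth$noise_sd), nvox, n)
  if (truth$ar1 != 0)
    series <- t(apply(series, 1, function(e)
      as.vector(stats::filter(e, truth$ar1, method = "recursive"))))
  series <- series + 100 + outer(rep(1, nvox), block_drive)
  if (truth$drift_sd > 0) {
    tt <- seq(-1, 1, length.out = n)
    basis <- cbind(tt, tt^2, tt^3)
    coefs <- matrix(stats::rnorm(nvox * 3, sd = truth$drift_sd), nvox, 3)
    series <- series + coefs %*% t(basis)
  }

  unitize <- function(v) if (sum(v^2) > 0) v / sqrt(sum(v^2)) else v
  sf <- truth$shared_fraction
  for (rn in names(truth$regions)) {
    vox <- truth$regions[[rn]]
    subj_pat <- unitize(stats::rnorm(length(vox)))
    pat <- unitize(sf * truth$group_patterns[[rn]] + (1 - sf) * subj_pat)
    series[vox, ] <- series[vox, ] +
      (truth$gains[[rn]] * pat) %*% t(task_mod)
    if (identical(rn, truth$encoding_region) && truth$score_encoding_gain > 0)
      series[vox, ] <- series[vox, ] +
        (truth$score_encoding_gain * score_z * truth$encoding_pattern) %*%
          t(enc_mod)
  }

  motion <- vapply(1:6, function(j)
    cumsum(stats::rnorm(n, sd = if (j <= 3) 0.01 else 2e-4)), numeric(n))
  if (truth$spike_prob > 0) {
    spikes <- which(stats::runif(n) < truth$spike_prob)
    for (s in spikes) {
      ax <- sample(1:3, 1)
      motion[s:n, ax] <- motion[s:n, ax] +
        truth$spike_magnitude * sign(stats::rnorm(1))
    }
  }
  structure(list(series = series, dim = truth$dim, motion = motion,
                 behavior = behavior, design = design, seed = as.integer(seed)),
            class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat("Subject data:", paste(x$dim, collapse = "x"), "grid,",
      ncol(x$series), "volumes; seed", x$seed, "\n")
  invisible(x)
}

#' Convert a subject's series to a 4-D array
#' @param x A `subject_data` object.
#' @export
series_array <- function(x) {
  stopifnot(inherits(x, "subject_data"))
  array(x$series, dim = c(x$dim, ncol(x$series)))
}

#' Simulate a multi-subject study
#'
#' Draws a behavioral table, z-scores the encoded measure within the sample,
#' and simulates each subject with [simulate_subject()] under per-subject
#' seeds derived deterministically from the study seed.
#'
#' @param n_subjects Number of subjects.
#' @param design,truth Study design and generative truth.
#' @param encoded_measure Behavior column whose z-score drives the pattern
#'   encoding (default `"sni_size"`).
#' @param group Sample label passed to [sample_behavior()].
#' @param behavior Optional pre-built behavior table (sampled if `NULL`).
#' @param seed Integer study seed.
#' @return A `study` object: `$subjects` (list of `subject_data`),
#'   `$behavior`, `$design`, `$truth`, `$seed`.
#' @export
simulate_study <- function(n_subjects, design, truth,
                           encoded_measure = "sni_size",
                           group = "DS", behavior = NULL, seed = 1L) {
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  if (is.null(behavior))
    behavior <- sample_behavior(n_subjects, group = group,
                                seed = sample.int(2^30, 1))
  score <- behavior[[encoded_measure]]
  if (is.null(score)) stop("behavior lacks encoded measure '", encoded_measure, "'")
  score_z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
    else rep(0, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(design, truth, score_z = score_z[i],
                     behavior = behavior[i, , drop = FALSE],
                     seed = subject_seeds[i]))
  names(subjects) <- behavior$subject
  structure(list(subjects = subjects, behavior = behavior, design = design,
                 truth = truth, encoded_measure = encoded_measure,
                 seed = as.integer(seed)), class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat("Simulated study:", length(x$subjects), "subjects, seed", x$seed, "\n")
  print(x$truth)
  invisible(x)
}
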