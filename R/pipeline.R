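#' Run the full synthetic-study analysis pipeline
#'
#' Executes the stages in dependency order on a simulated study:
#' `simulate` (generate subjects), `qc` (motion QC and spike frames), `glm`
#' (block-wise robust-WLS betas and social contrast), `decode-searchlight`
#' (per-subject, per-target accuracy maps), `discover-rois` (group
#' thresholding and clustering), `decode-roi` (ROI-wise decoding per
#' subject), `predict` (leave-one-participant-out nu-SVR of the encoded
#' score per ROI), `infer` (permutation p-values and FDR across ROIs) and
#' `report` (ROI-by-accuracy table with null percentiles). A stage that
#' needs a missing upstream product raises an error naming the stage to run
#' first. Artifacts (NIfTI maps and masks, CSV behavior, JSON results with a
#' provenance record) are written when `out_dir` is given.
#'
#' @param config Configuration list (see [default_config()]).
#' @param stages Character vector of stages to run, in order.
#' @param out_dir Optional artifact directory.
#' @param state Result list from a previous call (to run stage subsets).
#' @return The updated state list; `$report` holds the final table.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "qc", "glm",
                                    "decode-searchlight", "discover-rois",
                                    "decode-roi", "predict", "infer",
                                    "report"),
                         out_dir = NULL, state = list()) {
  validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  need <- function(what, stage_needed) {
    if (is.null(state[[what]]))
      stop("missing upstream product '", what, "': run stage '",
           stage_needed, "' first")
    state[[what]]
  }
  written <- character(0)
  emit <- function(obj, file, writer = jsonlite::write_json) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
  }

  for (stage in stages) {
    switch(stage,
      "simulate" = {
        sim <- config$simulation
        dmn <- config$grid$dim
        design <- make_block_design(
          n_blocks_per_condition = config$design$n_blocks_per_condition,
          stimuli_per_block = config$design$stimuli_per_block,
          tr = config$design$tr, targets = config$design$targets,
          seed = config$seed)
        regions <- sim$regions %||% list(
          region_a = region_box(dmn, round(dmn / 3), 2),
          region_b = region_box(dmn, round(2 * dmn / 3), 2))
        truth <- make_ground_truth(
          dim = dmn, voxel_size = config$grid$voxel_size, regions = regions,
          condition_effect_gain = sim$condition_effect_gain,
          shared_fraction = sim$shared_fraction,
          score_encoding_gain = sim$score_encoding_gain,
          noise_sd = sim$noise_sd, drift_sd = sim$drift_sd, ar1 = sim$ar1,
          spike_prob = sim$spike_prob,
          spike_magnitude = sim$spike_magnitude, seed = config$seed)
        state$study <- simulate_study(sim$n_subjects, design, truth,
                                      seed = config$seed)
        emit(state$study$behavior, "behavior.csv",
             function(x, p) utils::write.csv(x, p, row.names = FALSE))
        if (!is.null(out_dir)) {
          write_events_tsv(design, file.path(out_dir, "events.tsv"))
          written <- c(written, file.path(out_dir, "events.tsv"))
        }
        emit(list(regions = lapply(truth$regions, as.integer),
                  gains = as.list(truth$gains),
                  shared_fraction = truth$shared_fraction,
                  score_encoding_gain = truth$score_encoding_gain,
                  noise_sd = truth$noise_sd, seed = truth$seed),
             "ground_truth.json",
             function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE))
      },
      "qc" = {
        study <- need("study", "simulate")
        state$qc <- lapply(study$subjects, function(s)
          motion_qc(s$motion, tr = study$design$tr, series = s$series,
                    fd_translation_mm = config$qc$fd_translation_mm,
                    rotation_deg = config$qc$rotation_deg,
                    dvars_sd = config$qc$dvars_sd))
        state$outliers <- if (length(state$qc) >= 5)
          flag_outlier_participants(state$qc) else
          rep(FALSE, length(state$qc))
        emit(list(fd_p50 = vapply(state$qc, `[[`, 0, "fd_p50"),
                  fd_p95 = vapply(state$qc, `[[`, 0, "fd_p95"),
                  spike_frames = lapply(state$qc, `[[`, "spike_frames"),
                  outlier = state$outliers), "qc_report.json",
             function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE))
      },
      "glm" = {
        study <- need("study", "simulate")
        qc <- state$qc
        state$fits <- lapply(seq_along(study$subjects), function(i) {
          s <- study$subjects[[i]]
          dm <- build_design_matrix(
            study$design, hrf_params = config$glm$hrf,
            highpass_cutoff = config$glm$highpass_cutoff,
            motion = s$motion,
            spike_frames = if (!is.null(qc)) qc[[i]]$spike_frames else integer(0))
          fit_glm(s$series, dm,
                  method = if (config$glm$robust) "rwls" else "ols")
        })
        state$patterns <- lapply(state$fits, block_patterns)
        state$contrasts <- do.call(rbind,
                                   lapply(state$fits, contrast_image, "social"))
      },
      "decode-searchlight" = {
        patterns <- need("patterns", "glm")
        dmn <- config$grid$dim
        state$maps <- lapply(config$design$targets, function(tg)
          lapply(patterns, searchlight_decode, dim = dmn,
                 radius = config$decoding$radius, cost = config$decoding$cost,
                 target = tg))
        names(state$maps) <- config$design$targets
        if (!is.null(out_dir))
          for (tg in config$design$targets) {
            mean_map <- state$maps[[tg]][[1]]
            mean_map$values <- rowMeans(vapply(state$maps[[tg]],
                                               `[[`, numeric(length(mean_map$values)),
                                               "values"))
            write_volume(mean_map,
                         file.path(out_dir, paste0("accuracy_", tg, ".nii.gz")),
                         config$grid$voxel_size)
          }
      },
      "discover-rois" = {
        maps <- need("maps", "decode-searchlight")
        state$rois <- group_roi_discovery(
          maps, dim = config$grid$dim, alpha = config$decoding$alpha,
          cluster_k = config$decoding$cluster_k,
          n_perm = min(config$inference$n_perm, 5000L), seed = config$seed)
        if (!is.null(out_dir) && length(state$rois$rois)) {
          mask <- array(0, config$grid$dim)
          for (i in seq_along(state$rois$rois))
            mask[state$rois$rois[[i]]] <- i
          write_volume(mask, file.path(out_dir, "rois.nii.gz"),
                       config$grid$voxel_size)
          written <- c(written, file.path(out_dir, "rois.nii.gz"))
        }
      },
      "decode-roi" = {
        patterns <- need("patterns", "glm")
        rois <- need("rois", "discover-rois")
        state$roi_accuracy <- sapply(rois$rois, function(vox)
          vapply(patterns, function(p)
            decode_patterns(p$patterns[, vox, drop = FALSE],
                            labels = p$labels$inference,
                            cost = config$decoding$cost), 0))
        if (length(rois$rois) == 1)
          state$roi_accuracy <- matrix(state$roi_accuracy,
                                       dimnames = list(NULL, names(rois$rois)))
      },
      "predict" = {
        rois <- need("rois", "discover-rois")
        contrasts <- need("contrasts", "glm")
        if (!length(rois$rois))
          stop("no ROIs available for prediction: run 'discover-rois' ",
               "on data with decodable signal first")
        study <- need("study", "simulate")
        scores <- study$behavior[[study$encoded_measure]]
        state$predictions <- lapply(rois$rois, function(vox)
          lopo_svr(contrasts[, vox, drop = FALSE], scores,
                   nu = config$prediction$nu, cost = config$prediction$cost))
      },
      "infer" = {
        preds <- need("predictions", "predict")
        rois <- need("rois", "discover-rois")
        contrasts <- state$contrasts
        study <- state$study
        scores <- study$behavior[[study$encoded_measure]]
        set.seed(config$seed)
        perm_seeds <- sample.int(2^30, length(preds))
        state$predictions <- lapply(seq_along(preds), function(i)
          test_prediction(preds[[i]],
                          contrasts[, rois$rois[[i]], drop = FALSE], scores,
                          n_perm = config$inference$n_perm,
                          seed = perm_seeds[i]))
        names(state$predictions) <- names(preds)
        ps <- vapply(state$predictions, `[[`, 0, "p")
        fdr <- fdr_correct(ps, q = config$inference$q)
        for (i in seq_along(state$predictions)) {
          state$predictions[[i]]$p_adjusted <- fdr$p_adjusted[i]
          state$predictions[[i]]$fdr_significant <- fdr$rejected[i]
        }
      },
      "report" = {
        rois <- need("rois", "discover-rois")
        rep_df <- data.frame(roi = names(rois$rois),
                             n_voxels = vapply(rois$rois, length, 0L))
        if (!is.null(state$roi_accuracy))
          rep_df$decoding_accuracy <- colMeans(state$roi_accuracy)
        if (!is.null(state$predictions)) {
          rep_df$prediction_r <- vapply(state$predictions, `[[`, 0, "r")
          rep_df$r_squared <- vapply(state$predictions, `[[`, 0, "r_squared")
          rep_df$null_q05 <- vapply(state$predictions, `[[`, 0, "null_q05")
          rep_df$null_q95 <- vapply(state$predictions, `[[`, 0, "null_q95")
          rep_df$p <- vapply(state$predictions, `[[`, 0, "p")
          rep_df$p_adjusted <- vapply(state$predictions, `[[`, 0, "p_adjusted")
        }
        rownames(rep_df) <- NULL
        state$report <- rep_df
        emit(rep_df, "report.json",
             function(x, p) jsonlite::write_json(x, p, dataframe = "rows",
                                                 auto_unbox = TRUE))
        if (!is.null(out_dir)) {
          rec <- run_record(config, written)
          jsonlite::write_json(rec, file.path(out_dir, "run_record.json"),
                               auto_unbox = TRUE)
        }
      },
      stop("unknown stage: ", stage)
    )
  }
  state
}
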