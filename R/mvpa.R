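#' Integer offsets of a searchlight sphere
#'
#' All integer 3-D offsets with Euclidean norm at most `radius`, in
#' lexicographic order (x fastest). Radius 4 gives the standard 257-voxel
#' searchlight sphere.
#'
#' @param radius Sphere radius in voxel units (>= 0).
#' @return Integer matrix, one offset per row.
#' @export
sphere_offsets <- function(radius = 4) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  g <- g[order(g$z, g$y, g$x), ]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Leave-two-blocks-out cross-validation folds
#'
#' Enumerates every ordered (why block, how block) pair; each fold holds out
#' exactly one why block and one how block, training on the rest. The
#' enumeration is deterministic.
#'
#' @param labels Character vector of inference labels (`"why"`/`"how"`), or
#'   a `beta_patterns` object.
#' @return List of integer index vectors (the held-out pair per fold).
#' @export
leave_two_blocks_out_folds <- function(labels) {
  if (inherits(labels, "beta_patterns")) labels <- labels$labels$inference
  why <- which(labels == "why"); how <- which(labels == "how")
  if (!length(why) || !length(how)) stop("need blocks of both classes")
  folds <- list()
  for (i in why) for (j in how) folds[[length(folds) + 1L]] <- c(i, j)
  folds
}

# internal: labels -> +1 (why) / -1 (how)
inference_y <- function(labels) {
  y <- ifelse(labels == "why", 1L, -1L)
  if (!all(labels %in% c("why", "how"))) stop("labels must be why/how")
  as.integer(y)
}

#' Cross-validated linear-SVM decoding of block patterns
#'
#' Trains a linear support vector machine (fixed cost, default `c = 1`) on
#' the training blocks of each fold and classifies the held-out blocks;
#' accuracy is the mean percentage of held-out blocks classified correctly.
#' Patterns are used as estimated (no feature scaling) unless `scale = TRUE`
#' z-scores each voxel within the training set of every fold.
#'
#' @param patterns A `beta_patterns` object, or a blocks-by-voxels matrix
#'   (then `labels` is required).
#' @param folds Fold list from [leave_two_blocks_out_folds()] (the default).
#' @param cost SVM cost parameter.
#' @param labels Inference labels when `patterns` is a bare matrix.
#' @param scale Within-fold feature standardization flag.
#' @return Decoding accuracy in percent.
#' @export
decode_patterns <- function(patterns, folds = NULL, cost = 1, labels = NULL,
                            scale = FALSE) {
  if (inherits(patterns, "beta_patterns")) {
    labels <- patterns$labels$inference
    X <- patterns$patterns
  } else X <- as.matrix(patterns)
  y <- inference_y(labels)
  if (is.null(folds)) folds <- leave_two_blocks_out_folds(labels)
  for (f in folds) {
    tr_y <- y[-f]
    if (!any(tr_y > 0) || !any(tr_y < 0))
      stop("a fold has no training pattern for one class")
  }
  if (all(apply(X, 2, function(v) stats::var(v) == 0)))
    warning("all features constant across training patterns; decoding is degenerate")
  if (!scale) {
    K <- tcrossprod(X)
    return(.svc_cv_accuracy_gram(K, y, folds, cost))
  }
  correct <- 0L; total <- 0L
  for (f in folds) {
    mu <- colMeans(X[-f, , drop = FALSE])
    sg <- apply(X[-f, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    K <- tcrossprod(Xs)
    m <- .svc_fit_gram(K[-f, -f, drop = FALSE], y[-f], cost)
    d <- .svc_decision_gram(K[f, -f, drop = FALSE], y[-f], m$alpha, m$rho)
    correct <- correct + sum((d >= 0) == (y[f] > 0))
    total <- total + length(f)
  }
  100 * correct / total
}

# internal: sphere membership table for in-mask voxels
# vox_idx: linear indices of in-mask voxels; returns nvox x n_offsets matrix
# of 1-based positions into vox_idx (0 where outside mask/grid)
sphere_members <- function(dim, vox_idx, radius) {
  off <- sphere_offsets(radius)
  nv <- length(vox_idx)
  lookup <- integer(prod(dim))
  lookup[vox_idx] <- seq_len(nv)
  ix <- ((vox_idx - 1) %% dim[1]) + 1
  iy <- (((vox_idx - 1) %/% dim[1]) %% dim[2]) + 1
  iz <- ((vox_idx - 1) %/% (dim[1] * dim[2])) + 1
  out <- matrix(0L, nv, nrow(off))
  for (k in seq_len(nrow(off))) {
    nx <- ix + off[k, 1]; ny <- iy + off[k, 2]; nz <- iz + off[k, 3]
    ok <- nx >= 1 & nx <= dim[1] & ny >= 1 & ny <= dim[2] &
      nz >= 1 & nz <= dim[3]
    lin <- (nx - 1) + (ny - 1) * dim[1] + (nz - 1) * dim[1] * dim[2] + 1
    memb <- integer(nv)
    memb[ok] <- lookup[lin[ok]]
    out[, k] <- memb
  }
  out
}

#' Searchlight decoding accuracy map
#'
#' Slides a sphere of the given radius across every in-mask voxel, decodes
#' why vs. how from the sphere-restricted block patterns
#' ([decode_patterns()] with leave-two-blocks-out folds), and writes the
#' accuracy to the sphere's center voxel. Spheres are clipped at mask and
#' grid edges (all in-mask voxels keep a value); sphere membership uses
#' center-to-center distance in voxel units. Decoding can be restricted to
#' one target condition.
#'
#' @param patterns A `beta_patterns` object whose `$voxels` are linear
#'   indices into the grid.
#' @param dim Grid dimensions (length 3).
#' @param radius Sphere radius in voxels (default 4).
#' @param cost SVM cost.
#' @param target Optional single target condition (e.g. `"faces"`).
#' @return An `accuracy_map`: `$values` (% per in-mask voxel), `$voxels`,
#'   `$dim`, `$chance = 50`.
#' @export
searchlight_decode <- function(patterns, dim, radius = 4, cost = 1,
                               target = NULL) {
  stopifnot(inherits(patterns, "beta_patterns"))
  keep <- if (is.null(target)) seq_len(nrow(patterns$labels)) else
    which(patterns$labels$target == target)
  if (!length(keep)) stop("no blocks for target ", target)
  X <- patterns$patterns[keep, , drop = FALSE]
  labs <- patterns$labels$inference[keep]
  y <- inference_y(labs)
  folds <- leave_two_blocks_out_folds(labs)
  memb <- sphere_members(dim, patterns$voxels, radius)
  vals <- .searchlight_accuracy(X, y, memb, folds, cost)
  structure(list(values = vals, voxels = patterns$voxels, dim = dim,
                 chance = 50, radius = radius, target = target),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat("Accuracy map:", length(x$values), "voxels on a",
      paste(x$dim, collapse = "x"), "grid; mean",
      round(mean(x$values), 2), "% (chance", x$chance, "%)\n")
  invisible(x)
}

#' Convert an accuracy map (or ROI mask) to a 3-D array
#' @param x An `accuracy_map`.
#' @param fill Value outside the mask.
#' @export
map_array <- function(x, fill = NA_real_) {
  a <- array(fill, dim = x$dim)
  a[x$voxels] <- x$values
  a
}

# internal: 6-connected components of a voxel index set on a grid
connected_components <- function(vox, dim) {
  if (!length(vox)) return(list())
  inset <- logical(prod(dim)); inset[vox] <- TRUE
  comp <- integer(prod(dim))
  nbr_off <- c(-1, 1, -dim[1], dim[1], -dim[1] * dim[2], dim[1] * dim[2])
  ix <- function(v) ((v - 1) %% dim[1]) + 1
  iy <- function(v) (((v - 1) %/% dim[1]) %% dim[2]) + 1
  cl <- 0L
  for (v in vox) {
    if (comp[v] != 0L) next
    cl <- cl + 1L
    queue <- v; comp[v] <- cl
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (k in 1:6) {
        w <- u + nbr_off[k]
        if (w < 1 || w > prod(dim)) next
        # forbid wrap-around across grid faces
        if (k <= 2 && ix(w) != ix(u) + c(-1, 1)[k]) next
        if (k %in% 3:4 && iy(w) != iy(u) + c(-1, 1)[k - 2]) next
        if (inset[w] && comp[w] == 0L) { comp[w] <- cl; queue <- c(queue, w) }
      }
    }
  }
  split(vox, comp[vox])
}

#' Group-level ROI discovery from searchlight accuracy maps
#'
#' Voxel-wise one-sample test of accuracy above chance (50%) for each target
#' condition, with familywise-error control by max-statistic sign-flip
#' permutation of the per-subject deviations (Bonferroni available as an
#' alternative). Voxels significant in every target condition are
#' intersected; 6-connected components of at least `cluster_k` voxels become
#' named ROIs, ordered by peak mean accuracy and tie-broken by lexicographic
#' peak coordinates.
#'
#' @param maps_by_condition Named list (one element per target condition) of
#'   per-subject accuracy matrices (`subjects x voxels`) or lists of
#'   `accuracy_map` objects on a common voxel set.
#' @param dim Grid dimensions.
#' @param voxels Linear voxel indices of the map columns.
#' @param alpha Familywise voxel-level alpha (default 0.05).
#' @param cluster_k Minimum cluster extent in voxels (default 5).
#' @param n_perm Sign flips for the max-statistic null (default 5000).
#' @param method `"permutation"` (default) or `"bonferroni"`.
#' @param seed Seed for the sign flips.
#' @return An `roi_set`: named list of voxel index vectors in `$rois`, plus
#'   provenance (`$alpha`, `$cluster_k`, thresholds used).
#' @export
group_roi_discovery <- function(maps_by_condition, dim, voxels = NULL,
                                alpha = 0.05, cluster_k = 5, n_perm = 5000,
                                method = c("permutation", "bonferroni"),
                                seed = 1L) {
  method <- match.arg(method)
  as_mat <- function(m) {
    if (is.matrix(m)) return(m)
    if (is.null(voxels)) voxels <<- m[[1]]$voxels
    do.call(rbind, lapply(m, `[[`, "values"))
  }
  mats <- lapply(maps_by_condition, as_mat)
  ns <- nrow(mats[[1]])
  if (ns < 10) stop("need >= 10 subjects for group ROI discovery")
  if (is.null(voxels)) voxels <- seq_len(ncol(mats[[1]]))
  set.seed(seed)
  sig_by_cond <- lapply(mats, function(M) {
    D <- M - 50
    nv <- ncol(D)
    ss <- colSums(D^2)
    tstat <- function(m) m / sqrt(pmax(ss / ns - m^2, 1e-12) * ns / (ns - 1) / ns)
    t_obs <- tstat(colMeans(D))
    if (method == "bonferroni") {
      crit <- stats::qt(1 - alpha / nv, df = ns - 1)
      return(t_obs > crit)
    }
    signs <- matrix(sample(c(-1, 1), ns * n_perm, replace = TRUE), n_perm, ns)
    signs[1, ] <- 1           # include the identity flip
    Mperm <- (signs %*% D) / ns
    Tperm <- Mperm / sqrt(pmax(rep(ss / ns, each = n_perm) - Mperm^2, 1e-12) *
                            ns / (ns - 1) / ns)
    maxT <- apply(Tperm, 1, max)
    crit <- sort(maxT)[ceiling((1 - alpha) * n_perm)]
    t_obs > crit
  })
  sig <- Reduce(`&`, sig_by_cond)
  surviving <- voxels[sig]
  comps <- connected_components(surviving, dim)
  comps <- comps[vapply(comps, length, 0L) >= cluster_k]
  if (!length(comps)) {
    warning("no clusters survive thresholding; empty ROI set")
    rois <- list()
  } else {
    mean_acc <- Reduce(`+`, lapply(mats, colMeans)) / length(mats)
    acc_of <- stats::setNames(mean_acc, voxels)
    peak <- vapply(comps, function(cc) max(acc_of[as.character(cc)]), 0)
    peak_vox <- vapply(comps, function(cc)
      cc[which.max(acc_of[as.character(cc)])], 0)
    ord <- order(-peak, peak_vox)
    comps <- comps[ord]
    coords <- function(v) c(((v - 1) %% dim[1]) + 1,
                            (((v - 1) %/% dim[1]) %% dim[2]) + 1,
                            ((v - 1) %/% (dim[1] * dim[2])) + 1)
    nm <- vapply(peak_vox[ord], function(v)
      sprintf("roi_x%02dy%02dz%02d", coords(v)[1], coords(v)[2], coords(v)[3]),
      "")
    rois <- stats::setNames(comps, make.unique(nm))
  }
  structure(list(rois = rois, dim = dim, alpha = alpha,
                 cluster_k = cluster_k, method = method, n_perm = n_perm,
                 n_subjects = ns, seed = as.integer(seed)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", length(x$rois), "regions (alpha", x$alpha, ",",
      x$method, "correction, cluster threshold", x$cluster_k, ")\n")
  for (nm in names(x$rois))
    cat("  ", nm, ":", length(x$rois[[nm]]), "voxels\n")
  invisible(x)
}

#' Cross-sample decoding between two participant groups
#'
#' Two-fold cross-sample decoding: train the linear SVM on all labelled
#' block patterns of one group, test on every block pattern of the other,
#' and vice versa. Transfer succeeds only insofar as the two groups share a
#' common multivoxel code.
#'
#' @param patterns_a,patterns_b Stacked `beta_patterns` for each group (use
#'   [stack_patterns()] to pool subjects); voxel index lists must match.
#' @param cost SVM cost.
#' @return Named vector: accuracy `a_to_b` and `b_to_a` in percent.
#' @export
cross_sample_decode <- function(patterns_a, patterns_b, cost = 1) {
  if (!identical(patterns_a$voxels, patterns_b$voxels))
    stop("voxel index lists differ between groups; patterns are not aligned")
  one_way <- function(tr, te) {
    ytr <- inference_y(tr$labels$inference)
    yte <- inference_y(te$labels$inference)
    K <- tcrossprod(tr$patterns)
    m <- .svc_fit_gram(K, ytr, cost)
    d <- .svc_decision_gram(te$patterns %*% t(tr$patterns), ytr, m$alpha, m$rho)
    100 * mean((d >= 0) == (yte > 0))
  }
  c(a_to_b = one_way(patterns_a, patterns_b),
    b_to_a = one_way(patterns_b, patterns_a))
}

#' Pool block patterns across subjects
#'
#' Stacks the per-subject `beta_patterns` of a group into one pattern set
#' (rows = subject-blocks), preserving labels and checking voxel alignment.
#'
#' @param pattern_list List of `beta_patterns`.
#' @export
stack_patterns <- function(pattern_list) {
  v <- pattern_list[[1]]$voxels
  for (p in pattern_list)
    if (!identical(p$voxels, v)) stop("voxel index lists differ across subjects")
  structure(list(
    patterns = do.call(rbind, lapply(pattern_list, `[[`, "patterns")),
    labels = do.call(rbind, lapply(pattern_list, `[[`, "labels")),
    voxels = v), class = "beta_patterns")
}
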