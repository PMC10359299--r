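# shared fixtures: small designs and studies built in code at test time

ds_design <- function(seed = 1L)
  make_block_design(4, 8, tr = 1, seed = seed)

tiny_grid <- c(6, 6, 6)
tiny_roi <- list(r1 = 1:200)

# simulate a small study and return the per-subject social contrast images
# (subjects x voxels) plus the behavior table
contrast_study <- function(n_subjects, truth, design = ds_design(),
                           seed = 1L, contrast = "social") {
  st <- simulate_study(n_subjects, design, truth, seed = seed)
  contrasts <- t(vapply(st$subjects, function(su) {
    f <- fit_glm(su, build_design_matrix(design, motion = su$motion))
    contrast_image(f, contrast)
  }, numeric(prod(truth$dim))))
  list(contrasts = contrasts, behavior = st$behavior, study = st)
}

# brute-force Pearson correlation (oracle)
cor_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force Benjamini-Hochberg step-up (oracle)
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= q * seq_len(m) / m)
  rejected <- logical(m)
  if (length(k)) rejected[ord[seq_len(max(k))]] <- TRUE
  rejected
}

# exhaustive linear-separator oracle for 2-voxel toy problems: is any
# line able to classify the held-out points as the SVM route does?
brute_separator_accuracy <- function(X, y, folds) {
  stopifnot(ncol(X) == 2)
  correct <- 0L; total <- 0L
  for (f in folds) {
    tr <- setdiff(seq_len(nrow(X)), f)
    # search over directions; pick max-margin threshold
    best <- NULL; best_margin <- -Inf
    for (th in seq(0, pi, length.out = 721)) {
      w <- c(cos(th), sin(th))
      proj <- X[tr, ] %*% w
      pos <- proj[y[tr] > 0]; neg <- proj[y[tr] < 0]
      # orient so positives above
      if (min(pos) - max(neg) > best_margin) {
        best_margin <- min(pos) - max(neg)
        best <- list(w = w, b = -(min(pos) + max(neg)) / 2, s = 1)
      }
      if (min(neg) - max(pos) > best_margin) {
        best_margin <- min(neg) - max(pos)
        best <- list(w = w, b = -(min(neg) + max(pos)) / 2, s = -1)
      }
    }
    pred <- sign((X[f, , drop = FALSE] %*% best$w + best$b) * best$s)
    correct <- correct + sum(pred == y[f])
    total <- total + length(f)
  }
  100 * correct / total
}
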