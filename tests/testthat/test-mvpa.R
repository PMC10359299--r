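test_that("sphere offsets enumerate the integer lattice ball", {
  expect_equal(nrow(sphere_offsets(0)), 1)
  expect_equal(nrow(sphere_offsets(1)), 7)     # center + 6 face neighbors
  expect_equal(nrow(sphere_offsets(4)), 257)   # radius-4 searchlight
  off <- sphere_offsets(4)
  expect_true(all(rowSums(off^2) <= 16))
  # lattice-count oracle
  cnt <- sum(outer(outer((-4:4)^2, (-4:4)^2, "+"), (-4:4)^2, "+") <= 16)
  expect_equal(nrow(off), cnt)
  expect_error(sphere_offsets(-1), ">= 0")
})

test_that("leave-two-blocks-out enumerates all why-how pairs", {
  expect_length(leave_two_blocks_out_folds(rep(c("why", "how"), each = 4)), 16)
  expect_length(leave_two_blocks_out_folds(rep(c("why", "how"), each = 6)), 36)
  f1 <- leave_two_blocks_out_folds(c("why", "how"))
  expect_length(f1, 1)   # degenerate: fold exists but training is empty
  expect_error(decode_patterns(matrix(rnorm(4), 2), folds = f1,
                               labels = c("why", "how")),
               "no training pattern")
  # every fold holds out exactly one block of each class
  labs <- rep(c("why", "how"), each = 4)
  for (f in leave_two_blocks_out_folds(labs)) {
    expect_length(f, 2)
    expect_setequal(labs[f], c("why", "how"))
  }
})

test_that("decoding of separable patterns is perfect and label-symmetric", {
  set.seed(1)
  # large margin in one voxel, consistent across blocks
  X <- cbind(c(rep(5, 4), rep(-5, 4)) + rnorm(8, sd = 0.1),
             matrix(rnorm(8 * 20), 8))
  labs <- rep(c("why", "how"), each = 4)
  expect_equal(decode_patterns(X, labels = labs), 100)
  set.seed(2)
  Xr <- matrix(rnorm(8 * 10), 8)
  a1 <- decode_patterns(Xr, labels = labs)
  # consistent relabeling retrains a mirrored classifier: accuracy invariant
  flip <- ifelse(labs == "why", "how", "why")
  expect_equal(decode_patterns(Xr, labels = flip), a1)
  # flipping only the evaluation labels maps accuracy a -> 100 - a
  folds <- leave_two_blocks_out_folds(labs)
  y <- ifelse(labs == "why", 1L, -1L)
  K <- tcrossprod(Xr)
  correct_flip <- 0
  for (f in folds) {
    m <- blockmvpa:::.svc_fit_gram(K[-f, -f], y[-f], 1)
    d <- blockmvpa:::.svc_decision_gram(K[f, -f, drop = FALSE], y[-f],
                                        m$alpha, m$rho)
    correct_flip <- correct_flip + sum((d >= 0) == (y[f] < 0))
  }
  expect_equal(a1 + 100 * correct_flip / (2 * length(folds)), 100)
})

test_that("decoding accuracy is invariant to affine pattern rescaling", {
  set.seed(3)
  labs <- rep(c("why", "how"), each = 4)
  X <- rbind(matrix(rnorm(4 * 12, mean = 1), 4),
             matrix(rnorm(4 * 12, mean = -1), 4))
  a0 <- decode_patterns(X, labels = labs)
  a_scaled <- decode_patterns(X * 7, labels = labs)
  a_shifted <- decode_patterns(X + 100, labels = labs)
  expect_equal(a0, a_scaled)
  expect_equal(a0, a_shifted)
})

test_that("SVM route agrees with independent oracles", {
  skip_if_not_installed("e1071")
  labs <- rep(c("why", "how"), each = 6)
  y <- ifelse(labs == "why", 1, -1)
  set.seed(4)
  for (rep_i in 1:5) {
    # 2-voxel toy problems with clear class structure: the exhaustive
    # max-margin separator oracle and the soft-margin SVM route agree
    X <- matrix(rnorm(12 * 2, mean = rep(c(2, -2), each = 6)), 12)
    folds <- leave_two_blocks_out_folds(labs)
    expect_equal(decode_patterns(X, labels = labs),
                 brute_separator_accuracy(X, y, folds), tolerance = 1e-9)
  }
  # high-dimensional problems: e1071/libsvm fold-by-fold agreement
  set.seed(5)
  for (rep_i in 1:3) {
    X <- matrix(rnorm(12 * 40), 12)
    folds <- leave_two_blocks_out_folds(labs)
    ours <- decode_patterns(X, labels = labs, folds = folds)
    correct <- 0
    for (f in folds) {
      m <- e1071::svm(X[-f, ], factor(labs[-f], c("why", "how")),
                      kernel = "linear", cost = 1, scale = FALSE)
      correct <- correct + sum(predict(m, X[f, , drop = FALSE]) == labs[f])
    }
    expect_equal(ours, 100 * correct / (2 * length(folds)))
  }
})

test_that("searchlight at radius 0 reduces to single-voxel decoding", {
  set.seed(6)
  labs <- rep(c("why", "how"), each = 4)
  X <- matrix(rnorm(8 * 27), 8)
  pats <- structure(list(patterns = X,
                         labels = data.frame(block = paste0("b", 1:8),
                                             condition = labs,
                                             inference = labs,
                                             target = "faces"),
                         voxels = 1:27), class = "beta_patterns")
  am <- searchlight_decode(pats, dim = c(3, 3, 3), radius = 0)
  single <- vapply(1:27, function(v)
    decode_patterns(X[, v, drop = FALSE], labels = labs), 0)
  expect_equal(am$values, single)
  expect_true(all(am$values >= 0 & am$values <= 100))
})

test_that("searchlight localizes a planted effect and respects bounds", {
  set.seed(7)
  d <- make_block_design(4, 8, tr = 1)
  dmn <- c(10, 10, 10)
  reg <- list(r1 = region_box(dmn, c(5, 5, 5), 1))
  tr <- make_ground_truth(dim = dmn, regions = reg, condition_effect_gain = 1,
                          shared_fraction = 1, noise_sd = 1, seed = 11)
  su <- simulate_subject(d, tr, seed = 21)
  f <- fit_glm(su, build_design_matrix(d, motion = su$motion))
  p <- block_patterns(f)
  am <- searchlight_decode(p, dim = dmn, radius = 2, target = "faces")
  expect_true(all(am$values >= 0 & am$values <= 100))
  # the global maximum is attained inside the region's dilation by the
  # sphere radius, and accuracy is clearly elevated there
  coords <- function(v, dmn) cbind(((v - 1) %% dmn[1]) + 1,
                                   (((v - 1) %/% dmn[1]) %% dmn[2]) + 1,
                                   ((v - 1) %/% (dmn[1] * dmn[2])) + 1)
  cc <- coords(am$voxels, dmn)
  rc <- coords(reg$r1, dmn)
  dist_to_reg <- apply(cc, 1, function(p0)
    min(sqrt(colSums((t(rc) - p0)^2))))
  inside <- dist_to_reg <= 2
  expect_equal(max(am$values[inside]), max(am$values))
  expect_gt(mean(am$values[inside]), mean(am$values[!inside]) + 15)
})

test_that("group ROI discovery applies conjunction, FWE and cluster extent", {
  set.seed(8)
  dmn <- c(8, 8, 8)
  nv <- prod(dmn)
  ns <- 14
  reg <- region_box(dmn, c(4, 4, 4), 1)   # 27-voxel cube
  mk <- function(signal) {
    M <- matrix(rnorm(ns * nv, 50, 6), ns, nv)
    if (signal) M[, reg] <- M[, reg] + 30
    M
  }
  rois <- group_roi_discovery(list(faces = mk(TRUE), hands = mk(TRUE)),
                              dim = dmn, n_perm = 500, seed = 1)
  expect_equal(length(rois$rois), 1)
  jac <- length(intersect(rois$rois[[1]], reg)) /
    length(union(rois$rois[[1]], reg))
  expect_gte(jac, 0.5)
  # conjunction: signal in only one target condition yields nothing
  expect_warning(
    r0 <- group_roi_discovery(list(faces = mk(TRUE), hands = mk(FALSE)),
                              dim = dmn, n_perm = 500, seed = 1),
    "empty")
  expect_length(r0$rois, 0)
  # a 4-voxel component is excluded by the cluster threshold of five
  tiny <- region_box(dmn, c(2, 2, 2), c(1, 1, 0))[1:4]
  mk_tiny <- function() {
    M <- matrix(rnorm(ns * nv, 50, 6), ns, nv)
    M[, tiny] <- M[, tiny] + 40
    M
  }
  set.seed(9)
  expect_warning(
    r4 <- group_roi_discovery(list(faces = mk_tiny(), hands = mk_tiny()),
                              dim = dmn, n_perm = 500, seed = 2),
    "empty")
  expect_length(r4$rois, 0)
  expect_error(group_roi_discovery(list(f = mk(TRUE)[1:5, ]), dim = dmn),
               ">= 10 subjects")
})

test_that("cross-sample decoding transfers only shared codes", {
  set.seed(10)
  labs <- rep(c("why", "how"), each = 4)
  mkgrp <- function(shift) {
    pats <- lapply(1:4, function(i) {
      X <- matrix(rnorm(8 * 30, sd = 0.5), 8) +
        outer(ifelse(labs == "why", 1, -1), shift)
      structure(list(patterns = X,
                     labels = data.frame(block = paste0("b", 1:8),
                                         condition = labs, inference = labs,
                                         target = "faces"),
                     voxels = 1:30), class = "beta_patterns")
    })
    stack_patterns(pats)
  }
  shared <- rnorm(30)
  A <- mkgrp(shared); B <- mkgrp(shared)
  acc <- cross_sample_decode(A, B)
  expect_true(all(acc > 90))
  # self-transfer equals within-set training accuracy and is symmetric
  self <- cross_sample_decode(A, A)
  expect_equal(unname(self["a_to_b"]), unname(self["b_to_a"]))
  # mismatched voxel lists are refused
  B2 <- B; B2$voxels <- 31:60
  expect_error(cross_sample_decode(A, B2), "not aligned")
})
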