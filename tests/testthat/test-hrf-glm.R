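test_that("canonical HRF has the expected shape", {
  expect_equal(canonical_hrf(0), 0)
  tt <- seq(0, 32, by = 0.1)
  h <- canonical_hrf(tt)
  expect_equal(tt[which.max(h)], 5, tolerance = 0.11)  # peaks near 5 s
  expect_equal(max(h), 1)                              # unit peak
  expect_lt(abs(canonical_hrf(32)), 0.01)              # tail decays
  expect_error(canonical_hrf(1, delay = -1), "positive")
  expect_error(canonical_hrf(-1), "non-negative")
})

test_that("design matrix bookkeeping: task, drift, motion, spike columns", {
  d <- make_block_design(4, 8, tr = 1)
  motion <- matrix(rnorm(d$n_volumes * 6, sd = 0.01), ncol = 6)
  dm <- build_design_matrix(d, motion = motion, spike_frames = c(10, 50))
  k <- floor(2 * d$n_volumes * d$tr / 100)
  expect_equal(ncol(dm$X), 16 + k + 6 + 2 + 1)
  expect_false(anyDuplicated(colnames(dm$X)) > 0)
  # spike columns have exactly one nonzero entry, value 1
  expect_equal(sum(dm$X[, "spike10"]), 1)
  expect_equal(unname(dm$X[10, "spike10"]), 1)
  expect_error(build_design_matrix(d, motion = motion[-1, ]), "n_volumes x 6")
})

test_that("cosine drift basis removes slow trends but keeps block signal", {
  d <- make_block_design(4, 8, tr = 1)
  dm <- build_design_matrix(d)
  drift_cols <- grepl("^drift|^intercept", colnames(dm$X))
  tt <- (seq_len(d$n_volumes) - 1) * d$tr
  # slow sinusoid (period 300 s) is almost fully captured by the basis
  slow <- sin(2 * pi * tt / 300)
  fit <- stats::lm.fit(dm$X[, drift_cols, drop = FALSE], slow)
  expect_lt(sum(fit$residuals^2) / sum(slow^2), 0.01)
  # the why-minus-how effect survives projection on the drift space
  sgn <- ifelse(dm$block_info$inference == "why", 1, -1) / 8
  eff <- as.vector(dm$X[, dm$task_cols] %*% sgn)
  fit2 <- stats::lm.fit(dm$X[, drift_cols, drop = FALSE], eff)
  # counterbalancing is stochastic, so some low-frequency imbalance remains;
  # the bulk of the effect energy must survive (the joint GLM estimate
  # itself is unbiased, see the noiseless-recovery test)
  expect_gt(sum(fit2$residuals^2) / sum(eff^2), 0.75)
})

test_that("boxcar convolution matches an independent discrete oracle", {
  d <- make_block_design(1, 4, tr = 2)
  dm <- build_design_matrix(d, highpass_cutoff = NULL)
  b <- d$blocks[1, ]
  # direct discrete convolution oracle at dt = 0.1
  dt <- 0.1
  t_hi <- seq(0, d$n_volumes * d$tr, by = dt)
  box <- as.numeric(t_hi >= b$onset & t_hi < b$offset)
  h <- canonical_hrf(seq(0, 32, by = dt))
  ref <- numeric(length(t_hi))
  for (i in seq_along(t_hi)) {
    jmax <- min(i, length(h))
    ref[i] <- sum(box[i - seq_len(jmax) + 1] * h[seq_len(jmax)]) * dt
  }
  frame_idx <- round((seq_len(d$n_volumes) - 1) * d$tr / dt) + 1
  expect_equal(unname(dm$X[, b$block]), ref[frame_idx], tolerance = 1e-10)
})

test_that("GLM recovers known betas exactly from noiseless data", {
  d <- make_block_design(2, 4, tr = 1)
  dm <- build_design_matrix(d)
  set.seed(1)
  B_true <- matrix(rnorm(ncol(dm$X) * 30), ncol(dm$X), 30)
  series <- t(dm$X %*% B_true)        # voxels x time
  for (m in c("ols", "rwls")) {
    fit <- fit_glm(series, dm, method = m)
    expect_lt(max(abs(fit$betas - B_true)), 1e-8)
  }
})

test_that("robust WLS matches OLS under homoscedastic noise", {
  d <- make_block_design(2, 4, tr = 1)
  dm <- build_design_matrix(d)
  set.seed(2)
  B_true <- matrix(rnorm(ncol(dm$X) * 100), ncol(dm$X), 100)
  series <- t(dm$X %*% B_true + matrix(rnorm(nrow(dm$X) * 100), nrow(dm$X)))
  b_ols <- fit_glm(series, dm, method = "ols")$betas
  b_rwls <- fit_glm(series, dm, method = "rwls")$betas
  expect_lt(sqrt(mean((b_rwls - b_ols)^2)) / sqrt(mean(b_ols^2)), 0.02)
})

test_that("robust WLS beats OLS under heteroscedastic spike noise", {
  d <- make_block_design(2, 4, tr = 1)
  dm <- build_design_matrix(d)
  n <- nrow(dm$X)
  set.seed(3)
  rmse_ols <- rmse_rwls <- numeric(100)
  for (i in 1:100) {
    B_true <- matrix(rnorm(ncol(dm$X) * 20), ncol(dm$X), 20)
    noise <- matrix(rnorm(n * 20), n)
    bad <- sample(n, round(0.05 * n))
    noise[bad, ] <- noise[bad, ] * sqrt(10)   # 10x variance timepoints
    series <- t(dm$X %*% B_true + noise)
    rmse_ols[i] <- sqrt(mean((fit_glm(series, dm, "ols")$betas - B_true)^2))
    rmse_rwls[i] <- sqrt(mean((fit_glm(series, dm, "rwls")$betas - B_true)^2))
  }
  expect_lt(mean(rmse_rwls), mean(rmse_ols))
})

test_that("rank deficiency is reported with the collinear columns", {
  d <- make_block_design(2, 4, tr = 1)
  dm <- build_design_matrix(d)
  dm$X <- cbind(dm$X, dup = dm$X[, 1])
  expect_error(fit_glm(matrix(rnorm(10 * nrow(dm$X)), 10), dm), "collinear")
})

test_that("contrast images behave as weighted beta differences", {
  d <- make_block_design(2, 4, tr = 1)
  dm <- build_design_matrix(d)
  set.seed(4)
  fit <- fit_glm(t(dm$X %*% matrix(rnorm(ncol(dm$X) * 12), ncol(dm$X))), dm)
  info <- fit$block_info
  # all why betas equal to how betas -> zero image
  fit0 <- fit
  fit0$betas[info$block, ] <- matrix(rep(rnorm(12), each = nrow(info)),
                                     nrow(info))
  expect_equal(max(abs(contrast_image(fit0, "social"))), 0)
  # why = how + 1 -> image of ones
  fit1 <- fit0
  why_rows <- info$block[info$inference == "why"]
  fit1$betas[why_rows, ] <- fit1$betas[why_rows, ] + 1
  expect_equal(as.vector(unname(contrast_image(fit1, "social"))), rep(1, 12))
  # random betas match a hand-computed weighted mean at spot-checked voxels
  ci <- contrast_image(fit, "social")
  for (v in c(1, 3, 5, 7, 12)) {
    why_mean <- mean(fit$betas[info$block[info$inference == "why"], v])
    how_mean <- mean(fit$betas[info$block[info$inference == "how"], v])
    expect_equal(ci[v], why_mean - how_mean, tolerance = 1e-12)
  }
  # social contrast weights sum to zero by construction
  expect_equal(sum(c(rep(1 / 8, 8), rep(-1 / 8, 8))), 0)
  # nonsocial contrast unavailable in the 2-target variant
  expect_error(contrast_image(fit, "nonsocial"), "unavailable")
})
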