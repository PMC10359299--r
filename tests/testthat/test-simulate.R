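test_that("simulation is bit-identical under identical seeds", {
  d <- make_block_design(2, 4, tr = 1)
  tr <- make_ground_truth(dim = c(5, 5, 5),
                          regions = list(r = region_box(c(5, 5, 5), c(3, 3, 3), 1)),
                          condition_effect_gain = 0.5, noise_sd = 1,
                          drift_sd = 0.5, spike_prob = 0.01, seed = 3)
  s1 <- simulate_subject(d, tr, score_z = 0.7, seed = 42)
  s2 <- simulate_subject(d, tr, score_z = 0.7, seed = 42)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$motion, s2$motion)
  s3 <- simulate_subject(d, tr, score_z = 0.7, seed = 43)
  expect_false(identical(s1$series, s3$series))
  # study-level determinism
  st1 <- simulate_study(4, d, tr, seed = 5)
  st2 <- simulate_study(4, d, tr, seed = 5)
  expect_identical(st1$subjects[[3]]$series, st2$subjects[[3]]$series)
  expect_identical(st1$behavior, st2$behavior)
})

test_that("noiseless forward model plants exactly the advertised patterns", {
  d <- make_block_design(2, 4, tr = 1)
  dmn <- c(6, 6, 6)
  reg <- list(r = region_box(dmn, c(3, 3, 3), 1))
  tr <- make_ground_truth(dim = dmn, regions = reg, condition_effect_gain = 2,
                          shared_fraction = 1, noise_sd = 0, seed = 7)
  su <- simulate_subject(d, tr, seed = 1)
  expect_true(all(is.finite(su$series)))
  fit <- fit_glm(su$series, build_design_matrix(d, highpass_cutoff = NULL),
                 method = "ols")
  info <- fit$block_info
  why_hat <- colMeans(fit$betas[info$block[info$inference == "why"], ])
  how_hat <- colMeans(fit$betas[info$block[info$inference == "how"], ])
  diffp <- why_hat - how_hat
  # inside the region: exactly gain * unit pattern; outside: exactly zero
  expect_equal(diffp[reg$r], 2 * tr$group_patterns$r, tolerance = 1e-6)
  expect_lt(max(abs(diffp[-reg$r])), 1e-6)
})

test_that("zero condition gain leaves decoding at chance on average", {
  d <- make_block_design(2, 4, tr = 1)
  tr <- make_ground_truth(dim = c(5, 5, 5), regions = list(),
                          condition_effect_gain = 0, noise_sd = 1, seed = 1)
  accs <- vapply(1:25, function(s) {
    su <- simulate_subject(d, tr, seed = 100 + s)
    f <- fit_glm(su, build_design_matrix(d))
    decode_patterns(block_patterns(f, targets = "faces"))
  }, 0)
  expect_equal(mean(accs), 50, tolerance = 7)
})

test_that("zero encoding gain leaves contrast patterns uninformative", {
  d <- make_block_design(2, 4, tr = 1)
  dmn <- c(5, 5, 5)
  reg <- list(r = region_box(dmn, c(3, 3, 3), 1))
  # Monte-Carlo across studies: correlation between the planted-region
  # contrast pattern (projected on the would-be encoding direction) and the
  # score stays near zero
  rs <- vapply(1:30, function(s) {
    tr <- make_ground_truth(dim = dmn, regions = reg,
                            condition_effect_gain = 0.3,
                            score_encoding_gain = 0, noise_sd = 1, seed = s)
    st <- simulate_study(8, d, tr, seed = 200 + s)
    proj <- vapply(st$subjects, function(su) {
      f <- fit_glm(su, build_design_matrix(d))
      sum(contrast_image(f, "social")[reg$r] * tr$encoding_pattern)
    }, 0)
    cor(proj, st$behavior$sni_size)
  }, 0)
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("motion spikes appear at the configured rate and magnitude", {
  d <- make_block_design(4, 8, tr = 1)
  tr <- make_ground_truth(dim = c(4, 4, 4), regions = list(), noise_sd = 1,
                          spike_prob = 0.02, spike_magnitude = 2, seed = 2)
  su <- simulate_subject(d, tr, seed = 3)
  jumps <- apply(abs(diff(su$motion[, 1:3])), 1, max)
  expect_gt(sum(jumps > 1), 0)   # some step displacements present
  sf <- spike_frames(su$motion)
  expect_true(all(sf >= 1 & sf <= nrow(su$motion)))
})

test_that("invalid ground-truth parameters are rejected", {
  expect_error(make_ground_truth(regions = list(r = 1:10),
                                 condition_effect_gain = -1), "gains")
  expect_error(make_ground_truth(shared_fraction = 1.4), "shared_fraction")
  expect_error(make_ground_truth(dim = c(3, 3, 3),
                                 regions = list(r = 1:100)), "outside grid")
  expect_error(make_ground_truth(regions = list(r = 1:5),
                                 encoding_region = "nope"), "encoding_region")
})
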