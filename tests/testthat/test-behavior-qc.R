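test_that("behavioral sampling hits its target moments and correlation", {
  b <- sample_behavior(10000, target_corr = 0.16, seed = 1)
  expect_true(all(b$sni_size >= 0))
  expect_true(all(b$sni_size == round(b$sni_size)))
  expect_false(anyDuplicated(b$subject) > 0)
  expect_equal(cor(b$aq, b$sni_size), 0.16, tolerance = 0.03)
  expect_equal(mean(b$sni_size), 16.68, tolerance = 0.4)
  expect_equal(sd(b$sni_size), 10.23, tolerance = 0.4)

  b0 <- sample_behavior(10000, target_corr = 0, seed = 2)
  expect_equal(cor(b0$aq, b0$sni_size), 0, tolerance = 0.03)

  expect_error(sample_behavior(10000, target_corr = 1.2), "< 1")
  expect_error(sample_behavior(2), "3 subjects")
  asd <- sample_behavior(50, group = "ASD", seed = 3)
  expect_true(all(asd$ados_sa >= 1 & asd$ados_sa <= 10))
})

test_that("d-prime matches the inverse-normal definition", {
  # hit rate 0.9772, false alarms 0.5 -> d' ~ 2 (no correction)
  expect_equal(dprime(9772, 10000, 5000, 10000, correction = "none"), 2,
               tolerance = 0.01)
  # log-linear correction keeps perfect rates finite
  expect_true(is.finite(dprime(10, 10, 0, 10)))
  expect_equal(dprime(6, 10, 3, 10, correction = "none"),
               qnorm(0.6) - qnorm(0.3), tolerance = 1e-12)
})

test_that("behavioral summary applies the omission and RT trimming rules", {
  trials <- data.frame(
    condition = "why_faces",
    response = c(rep("yes", 9), NA),
    correct_response = rep("yes", 10),
    rt = c(runif(9, 0.4, 0.8), NA))
  s <- behavioral_summary(trials)
  expect_equal(s$accuracy, 100)       # no-response omitted from denominator
  expect_equal(s$omission_rate, 10)
  # RTs beyond 3 SD of the condition mean are excluded from the mean
  rts <- c(rep(0.5, 20), 5)
  trials2 <- data.frame(condition = "how_faces", response = "yes",
                        correct_response = "yes", rt = rts)
  s2 <- behavioral_summary(trials2)
  expect_equal(s2$mean_rt, mean(rts[abs(rts - mean(rts)) <= 3 * sd(rts)]))
  # a condition with zero scorable trials warns and yields NA, not an error
  trials3 <- data.frame(condition = "why_hands", response = NA_character_,
                        correct_response = "yes", rt = NA_real_)
  expect_warning(s3 <- behavioral_summary(trials3), "no scorable")
  expect_true(is.na(s3$accuracy))
})

test_that("Box-Cox limits behave: lambda 0 is log, lambda 1 is affine", {
  x <- c(0.7, 0.8, 0.95, 0.99)
  expect_equal(as.numeric(boxcox_transform(x, lambda = 0)), log(x))
  y <- boxcox_transform(x, lambda = 1)
  expect_equal(as.numeric(y), x - 1)
  expect_equal(rank(as.numeric(y)), rank(x))
  expect_error(boxcox_transform(c(-1, 2)), "positive")
  # ML lambda is found for skewed data
  set.seed(1)
  z <- 1 - rbeta(200, 5, 1.2) + 0.01
  expect_true(is.finite(attr(boxcox_transform(z), "lambda")))
})

test_that("Butterworth low-pass matches its analytic magnitude response", {
  fs <- 2  # Hz
  n <- 4000
  tt <- (0:(n - 1)) / fs
  dc <- butterworth_lowpass(rep(3, n), sampling_hz = fs)
  expect_equal(dc[500:3500], rep(3, 3001), tolerance = 1e-6)  # DC gain 1
  # amplitude estimated by regressing on the quadrature pair (the sampled
  # peak underestimates the amplitude at 5 samples/cycle)
  fit_amp <- function(y, f) {
    tw <- tt[500:3500]
    b <- coef(lm(y ~ sin(2 * pi * f * tw) + cos(2 * pi * f * tw) - 1))
    sqrt(sum(b^2))
  }
  # sinusoid at the cutoff: squared single-pass gain = 1/2
  x <- sin(2 * pi * 0.2 * tt)
  yf <- butterworth_lowpass(x, sampling_hz = fs)
  expect_equal(fit_amp(yf[500:3500], 0.2), 0.5, tolerance = 0.01)
  # at twice the cutoff the attenuation is |H|^2 = 1/(1+2^10)
  x2 <- sin(2 * pi * 0.4 * tt)
  y2 <- butterworth_lowpass(x2, sampling_hz = fs)
  expect_lt(fit_amp(y2[500:3500], 0.4), 0.002)
  expect_error(butterworth_lowpass(x, cutoff_hz = 1.1, sampling_hz = fs),
               "Nyquist")
})

test_that("framewise displacement follows the differential-sum convention", {
  m <- matrix(0, 50, 6)
  expect_equal(framewise_displacement(m), rep(0, 50))
  m[20:50, 1] <- 0.2    # single x-translation step
  fd <- framewise_displacement(m)
  expect_equal(fd[20], 0.2)
  expect_equal(sum(fd != 0), 1)
  m2 <- matrix(0, 50, 6)
  m2[30:50, 5] <- 0.01  # 0.01 rad rotation -> 0.5 mm on a 50 mm sphere
  expect_equal(framewise_displacement(m2)[30], 0.5)
  expect_error(framewise_displacement(matrix(0, 10, 5)), "6 columns")
})

test_that("DVARS matches a direct brute-force computation", {
  s <- matrix(5, 30, 20)
  expect_equal(dvars(s), rep(0, 20))
  s2 <- s; s2[, 10:20] <- s2[, 10:20] + 3   # uniform +3 jump at frame 10
  expect_equal(dvars(s2)[10], 3)
  set.seed(1)
  s3 <- matrix(rnorm(600), 30)
  ref <- c(0, sapply(2:20, function(t) sqrt(mean((s3[, t] - s3[, t - 1])^2))))
  expect_equal(dvars(s3), ref, tolerance = 1e-10)
  expect_error(dvars(s3, mask = integer(0)), "empty mask")
})

test_that("spike frames equal the set defined by the separate thresholds", {
  n <- 60
  m <- matrix(0, n, 6)
  m[10:n, 1] <- 0.6                    # translation spike at frame 10
  m[25:n, 4] <- 0.6 * pi / 180         # 0.6 degree rotation at frame 25
  set.seed(2)
  series <- matrix(rnorm(50 * n), 50, n)
  series[, 40] <- series[, 40] + 10    # DVARS spike at frame 40
  got <- spike_frames(m, series)
  v <- dvars(series)
  dv_frames <- which(v > mean(v) + 2.5 * sd(v))
  expect_setequal(got, sort(unique(c(10, 25, dv_frames))))
  expect_true(40 %in% got)
  # sub-threshold motion is not flagged
  m_ok <- matrix(0, n, 6); m_ok[15:n, 2] <- 0.4
  expect_length(spike_frames(m_ok), 0)
})

test_that("density-based outlier flagging isolates extreme movers", {
  set.seed(3)
  stats_ok <- data.frame(fd_p50 = 0.1 + 0.005 * runif(12),
                         fd_p95 = 0.3 + 0.01 * runif(12))
  expect_false(any(flag_outlier_participants(stats_ok)))
  # identical stats: one dense cluster, none flagged
  same <- data.frame(fd_p50 = rep(0.1, 8), fd_p95 = rep(0.3, 8))
  expect_false(any(flag_outlier_participants(same)))
  # one subject at 10x everyone's p95 is flagged (documented eps/min_pts)
  bad <- rbind(stats_ok, data.frame(fd_p50 = 1, fd_p95 = 3))
  flags <- flag_outlier_participants(bad, min_pts = 4)
  expect_true(flags[13])
  expect_false(any(flags[1:12]))
  # deterministic given inputs
  expect_identical(flags, flag_outlier_participants(bad, min_pts = 4))
  expect_error(flag_outlier_participants(stats_ok[1:4, ]), "few subjects")
})

test_that("motion QC pipeline produces ordered FD percentiles", {
  set.seed(4)
  motion <- matrix(cumsum(rnorm(600, sd = 0.01)), 100, 6)
  qc <- motion_qc(motion, tr = 1)
  expect_true(all(qc$fd >= 0))
  expect_lte(qc$fd_p50, qc$fd_p95)
})
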