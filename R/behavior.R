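#' Sample a behavioral score table
#'
#' Draws per-subject behavioral measures through a Gaussian copula so that
#' marginal shapes and the target AQ-network-size correlation can be
#' controlled independently. Network size (SNI, people contacted at least
#' fortnightly) uses a negative-binomial margin; questionnaire and IQ scores
#' use rounded normal margins. Defaults emulate a neurotypical community
#' sample (network size about 16.7 +/- 10.2, AQ about 15.6 +/- 2.7,
#' full-scale IQ about 108 +/- 10); autism-severity scores are added for the
#' `"ASD"` group.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param target_corr Target correlation between AQ and SNI scores
#'   (`|target_corr| < 1`; default 0.16, a near-zero association).
#' @param sni_mean,sni_sd Moments of the network-size margin.
#' @param aq_mean,aq_sd,iq_mean,iq_sd Normal margins for AQ and IQ.
#' @param group Group label: `"DS"`, `"RS1"`, `"RS2"` or `"ASD"`.
#' @param seed Integer seed.
#' @return A `data.frame` with subject ids, `sni_size`, `aq`, `iq`, `group`,
#'   and (for ASD) `ados_sa`, `ados_rrb`.
#' @export
sample_behavior <- function(n_subjects, target_corr = 0.16,
                            sni_mean = 16.68, sni_sd = 10.23,
                            aq_mean = 15.55, aq_sd = 2.73,
                            iq_mean = 108.14, iq_sd = 10.14,
                            group = c("DS", "RS1", "RS2", "ASD"),
                            seed = 1L) {
  group <- match.arg(group)
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (abs(target_corr) >= 1) stop("|target_corr| must be < 1")
  R <- matrix(c(1, target_corr, target_corr, 1), 2)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("correlation matrix not positive semidefinite")
  set.seed(seed)
  L <- chol(R)
  Z <- matrix(stats::rnorm(n_subjects * 2), ncol = 2) %*% L
  u_sni <- stats::pnorm(Z[, 1])
  # negative-binomial margin for the contact count
  v <- sni_sd^2
  size <- if (v > sni_mean) sni_mean^2 / (v - sni_mean) else 1e6
  sni <- stats::qnbinom(u_sni, size = size, mu = sni_mean)
  aq <- round(aq_mean + aq_sd * Z[, 2])
  iq <- round(stats::rnorm(n_subjects, iq_mean, iq_sd))
  out <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n_subjects)),
    sni_size = as.integer(sni), aq = aq, iq = iq, group = group,
    stringsAsFactors = FALSE)
  if (group == "ASD") {
    out$ados_sa <- pmin(10L, pmax(1L, round(stats::rnorm(n_subjects, 7.52, 1.50))))
    out$ados_rrb <- pmin(10L, pmax(0L, round(stats::rnorm(n_subjects, 6.86, 2.51))))
  }
  stopifnot(all(out$sni_size >= 0), !anyDuplicated(out$subject))
  out
}

#' Sensitivity index d-prime with log-linear correction
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`; rates are corrected by
#' the log-linear rule (add 0.5 to each count, 1 to each denominator) so
#' perfect rates of 0 or 1 remain finite.
#'
#' @param n_hit,n_signal Hits and signal-trial count.
#' @param n_fa,n_noise False alarms and noise-trial count.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @export
dprime <- function(n_hit, n_signal, n_fa, n_noise,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (correction == "loglinear") {
    h <- (n_hit + 0.5) / (n_signal + 1)
    f <- (n_fa + 0.5) / (n_noise + 1)
  } else {
    h <- n_hit / n_signal
    f <- n_fa / n_noise
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Box-Cox transform with maximum-likelihood lambda
#'
#' Profile-likelihood estimate of the Box-Cox exponent (via an intercept-only
#' model) applied to a positive vector; `lambda = 0` reduces to the log.
#'
#' @param x Positive numeric vector.
#' @param lambda Fixed exponent; `NULL` (default) estimates it by ML.
#' @return Transformed vector with attribute `"lambda"`.
#' @export
boxcox_transform <- function(x, lambda = NULL) {
  if (any(x <= 0)) stop("Box-Cox requires positive values")
  if (is.null(lambda)) {
    df <- data.frame(.bc_x = as.numeric(x))
    bc <- MASS::boxcox(.bc_x ~ 1, data = df, lambda = seq(-5, 5, 0.01),
                       plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
  }
  y <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  attr(y, "lambda") <- lambda
  y
}

#' Per-condition behavioral performance summary
#'
#' Summarizes a trial table into per-condition accuracy, d-prime and mean
#' response time. Trials without a response are omitted from the accuracy
#' denominator (their rate is reported separately); RT means exclude values
#' more than 3 SDs from the condition mean; accuracy can optionally be
#' Box-Cox transformed for group statistics.
#'
#' @param trials Data frame with columns `condition`, `response`
#'   (`"yes"`/`"no"`/`NA` for no response), `correct_response`
#'   (`"yes"`/`"no"`) and `rt` (seconds, `NA` when no response).
#' @param boxcox Also return Box-Cox-transformed accuracy proportions.
#' @return Data frame with one row per condition: `accuracy` (%), `dprime`,
#'   `mean_rt`, `omission_rate` (%), `n_trials`.
#' @export
behavioral_summary <- function(trials, boxcox = FALSE) {
  need <- c("condition", "response", "correct_response", "rt")
  if (!all(need %in% names(trials)))
    stop("trial table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(trials, trials$condition), function(d) {
    scorable <- !is.na(d$response)
    n <- nrow(d)
    if (!any(scorable)) {
      warning("condition '", d$condition[1], "' has no scorable trials")
      return(data.frame(condition = d$condition[1], accuracy = NA_real_,
                        dprime = NA_real_, mean_rt = NA_real_,
                        omission_rate = 100, n_trials = n))
    }
    s <- d[scorable, ]
    acc <- 100 * mean(s$response == s$correct_response)
    sig <- s$correct_response == "yes"
    dp <- dprime(sum(s$response == "yes" & sig), sum(sig),
                 sum(s$response == "yes" & !sig), sum(!sig))
    rt <- s$rt[!is.na(s$rt)]
    if (length(rt)) {
      keep <- abs(rt - mean(rt)) <= 3 * stats::sd(rt) | length(rt) < 3
      keep[is.na(keep)] <- TRUE
      mrt <- mean(rt[keep])
    } else mrt <- NA_real_
    data.frame(condition = d$condition[1], accuracy = acc, dprime = dp,
               mean_rt = mrt, omission_rate = 100 * mean(!scorable),
               n_trials = n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (boxcox && all(is.finite(res$accuracy)) && all(res$accuracy > 0))
    res$accuracy_boxcox <- as.numeric(boxcox_transform(res$accuracy / 100))
  res
}
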