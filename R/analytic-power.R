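# Closed-form noncentral-t outcome probabilities. These serve both as the
# fast path for planning and as the independent oracle that the
# Monte-Carlo engine is tested against.

power_triple <- function(delta, df, alpha) {
  tc <- stats::qt(1 - alpha / 2, df)
  p_upper <- stats::pt(tc, df, ncp = delta, lower.tail = FALSE)
  p_lower <- stats::pt(-tc, df, ncp = delta)
  p_nonsig <- stats::pt(tc, df, ncp = delta) - p_lower
  # orient "in direction" along sign(delta); delta = 0 splits symmetrically
  if (delta >= 0) {
    c(p_sig_in_direction = p_upper, p_sig_wrong_direction = p_lower,
      p_nonsig = p_nonsig)
  } else {
    c(p_sig_in_direction = p_lower, p_sig_wrong_direction = p_upper,
      p_nonsig = p_nonsig)
  }
}

#' Outcome probabilities of a two-sample t test
#'
#' Splits the sampling distribution of the two-sample t statistic under a
#' standardized true difference `d` into the probabilities of a
#' significant result in the direction of `d`, a significant result in the
#' wrong direction, and a non-significant result. Uses the noncentral t
#' with noncentrality `d * sqrt(n1 n2 / (n1 + n2))` and
#' `df = n1 + n2 - 2`.
#'
#' @param d Standardized between-condition difference
#'   (`(muA - muB) / sigma_pooled`).
#' @param n1,n2 Per-condition sample sizes, each at least 2.
#' @param alpha Two-sided significance level.
#'
#' @return Named numeric vector `p_sig_in_direction`,
#'   `p_sig_wrong_direction`, `p_nonsig`; the three sum to 1.
#' @examples
#' power_two_sample(0.5, 64, 64)  # ~0.80 power, the textbook benchmark
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2)
  delta <- d * sqrt(n1 * n2 / (n1 + n2))
  power_triple(delta, n1 + n2 - 2, alpha)
}

#' Outcome probabilities of a paired t test
#'
#' As [power_two_sample()] but for the paired design: noncentrality
#' `dz * sqrt(n)` with `df = n - 1`, where `dz` is the mean of the paired
#' differences divided by their standard deviation.
#'
#' @param dz Standardized mean of paired differences.
#' @param n Number of pairs, at least 2.
#' @inheritParams power_two_sample
#' @return Named numeric vector as in [power_two_sample()].
#' @export
power_paired <- function(dz, n, alpha = 0.05) {
  stopifnot(n >= 2)
  power_triple(dz * sqrt(n), n - 1, alpha)
}

# Population-level signed effect size of one test under a design.
# Between: d = (muA - muB) / sigma_pooled with per-condition SDs weighted
# by (n - 1). Within: dz = (mu1 - mu2) / sd(diff), with
# sd(diff) = sqrt(s1^2 + s2^2 - 2 rho s1 s2).
design_effect <- function(design, spec) {
  ci <- resolve_condition(design, spec$condition)
  mi <- resolve_measure(design, spec$measure)
  condA <- design$conditions[[ci]]
  if (spec$kind == "between") {
    cj <- resolve_condition(design, spec$condition_b)
    condB <- design$conditions[[cj]]
    s2p <- ((condA$n - 1) * condA$model$sds[mi]^2 +
            (condB$n - 1) * condB$model$sds[mi]^2) / (condA$n + condB$n - 2)
    d <- (condA$model$means[mi] - condB$model$means[mi]) / sqrt(s2p)
    list(kind = "between", d = d, n1 = condA$n, n2 = condB$n)
  } else {
    mj <- resolve_measure(design, spec$measure_b)
    s1 <- condA$model$sds[mi]; s2 <- condA$model$sds[mj]
    rho <- condA$model$correlations[mi, mj]
    sdd <- sqrt(s1^2 + s2^2 - 2 * rho * s1 * s2)
    dz <- (condA$model$means[mi] - condA$model$means[mj]) / sdd
    list(kind = "within", dz = dz, n = condA$n)
  }
}

#' Analytic probability that one test meets its requirement
#'
#' Computes, from a design's population parameters alone, the probability
#' that the test named by `spec` produces the outcome the criterion
#' requires: significance with the expected sign, or non-significance.
#' This is exact for a single test (the Monte-Carlo engine is needed only
#' for the joint probability of several dependent tests).
#'
#' @param design A [study_design()] supplying population means, SDs,
#'   correlations and sample sizes.
#' @param spec A [test_spec()] resolving against `design`.
#' @param enforce_direction For significance requirements, count only the
#'   expected sign (default) or either sign.
#'
#' @return A single probability.
#' @seealso [estimate_success()] for the simulated joint probability.
#' @export
prob_outcome <- function(design, spec, enforce_direction = TRUE) {
  assert_valid(design, success_criterion(list(spec)))
  eff <- design_effect(design, spec)
  tri <- if (eff$kind == "between") {
    power_two_sample(eff$d, eff$n1, eff$n2, spec$alpha)
  } else {
    power_paired(eff$dz, eff$n, spec$alpha)
  }
  if (spec$required == "nonsignificant") {
    return(unname(tri["p_nonsig"]))
  }
  sig_total <- tri[["p_sig_in_direction"]] + tri[["p_sig_wrong_direction"]]
  if (!enforce_direction) return(sig_total)
  true_delta <- if (eff$kind == "between") eff$d else eff$dz
  true_sign <- if (true_delta >= 0) "positive" else "negative"
  if (identical(spec$expected_sign, true_sign)) {
    tri[["p_sig_in_direction"]]
  } else {
    tri[["p_sig_wrong_direction"]]
  }
}
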