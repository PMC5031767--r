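# Deterministic t-test computations and classification of an observed
# result against the outcome a success criterion requires from it.

test_result <- function(test_id, statistic, df, p_value, direction,
                        significant) {
  structure(
    list(test_id = test_id, statistic = statistic, df = df,
         p_value = p_value, direction = direction, significant = significant),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: t = %.4f, df = %.2f, p = %.4g (%s, %s)\n",
              x$test_id, x$statistic, x$df, x$p_value, x$direction,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

direction_of <- function(delta) {
  if (delta > 0) "positive" else if (delta < 0) "negative" else "zero"
}

#' Two-sample t test returning a classified result
#'
#' Computes the pooled-variance (Student) or Welch two-sample t test of
#' `xs` versus `ys` with a two-sided p value. The statistic's sign follows
#' the difference `mean(xs) - mean(ys)`.
#'
#' @param xs,ys Numeric vectors, each of length at least 2 and not both
#'   constant.
#' @param variant `"pooled"` (df = n1 + n2 - 2, the default, matching the
#'   analysis conventions of the source studies) or `"welch"`
#'   (Welch–Satterthwaite df).
#' @param alpha Two-sided significance level; `significant` is `p < alpha`
#'   (strict).
#' @param test_id Identifier carried into the result.
#'
#' @return A `test_result` with fields `statistic`, `df`, `p_value`,
#'   `direction` and `significant`.
#' @examples
#' two_sample_t(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))  # t = -2, df = 8
#' @export
two_sample_t <- function(xs, ys, variant = c("pooled", "welch"),
                         alpha = 0.05, test_id = "two_sample") {
  variant <- match.arg(variant)
  n1 <- length(xs); n2 <- length(ys)
  if (n1 < 2L || n2 < 2L) {
    tg_stop("N_TOO_SMALL", "each sample needs at least 2 observations")
  }
  v1 <- stats::var(xs); v2 <- stats::var(ys)
  delta <- mean(xs) - mean(ys)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 <= 0) {
      tg_stop("DEGENERATE_SAMPLE",
              "zero pooled variance: both samples are constant")
    }
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) {
      tg_stop("DEGENERATE_SAMPLE",
              "zero variance in both samples")
    }
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df)
  test_result(test_id, t, df, p, direction_of(delta), p < alpha)
}

#' Paired t test on a vector of within-subject differences
#'
#' One-sample t test of the differences against zero: the within-subjects
#' comparison of two correlated measures after differencing.
#'
#' @param diffs Numeric vector of paired differences, length at least 2,
#'   not all equal.
#' @inheritParams two_sample_t
#'
#' @return A `test_result`; `direction` is the sign of `mean(diffs)`.
#' @examples
#' paired_t(c(1, 2, 3))  # t = 2 / (1 / sqrt(3)) ~ 3.46, df = 2
#' @export
paired_t <- function(diffs, alpha = 0.05, test_id = "paired") {
  n <- length(diffs)
  if (n < 2L) {
    tg_stop("N_TOO_SMALL", "a paired test needs at least 2 differences")
  }
  s <- stats::sd(diffs)
  if (s == 0) {
    tg_stop("DEGENERATE_SAMPLE", "all paired differences are equal")
  }
  m <- mean(diffs)
  t <- m / (s / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  test_result(test_id, t, df, p, direction_of(m), p < alpha)
}

#' Does an observed test result meet its required outcome?
#'
#' A significance requirement is met only when the result is significant
#' AND its observed direction matches the expected sign — a significant
#' effect in the wrong direction does not replicate the original pattern.
#' A non-significance requirement is met when the result is not
#' significant. With `enforce_direction = FALSE` a significance
#' requirement accepts either direction.
#'
#' @param result A `test_result` produced under `spec`'s alpha.
#' @param spec The [test_spec()] stating the requirement.
#' @param enforce_direction Require the observed sign to match
#'   `expected_sign` for significance requirements (default `TRUE`).
#'
#' @return `TRUE` or `FALSE`.
#' @export
meets_requirement <- function(result, spec, enforce_direction = TRUE) {
  if (spec$required == "nonsignificant") {
    return(!result$significant)
  }
  if (!result$significant) return(FALSE)
  if (!enforce_direction) return(TRUE)
  identical(result$direction, spec$expected_sign)
}
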