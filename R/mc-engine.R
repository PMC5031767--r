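# Monte-Carlo engine: draws simulated direct replications of a study
# design and estimates the probability that the full success criterion is
# met. The estimate path is vectorised across replications — per
# condition, all replications' draws are generated as one standard-normal
# block and reduced to the per-replication moments the t tests need — so
# 100,000 replications of a small factorial study take seconds.

#' Draw one simulated sample for a condition
#'
#' Participants are independent draws from the multivariate normal
#' distribution defined by the condition's measure model: covariance
#' `Sigma[i, j] = sds[i] * sds[j] * correlations[i, j]`. Uses the current
#' RNG state of the session, so wrap in [withr::with_seed()] or
#' `set.seed()` for reproducibility.
#'
#' @param cond A [condition_spec()] that passes validation.
#' @return A data frame with `cond$n` rows and one column per measure.
#' @examples
#' cond <- condition_spec("demo", 5, measure_model(c("a", "b"),
#'   means = c(10, 20), sds = c(1, 1)))
#' set.seed(1)
#' sample_condition(cond)
#' @export
sample_condition <- function(cond) {
  model <- cond$model
  v <- validate_measure_model(model, sprintf("condition '%s'", cond$label))
  if (nrow(v) > 0L || cond$n < 2) {
    tg_stop("INVALID_DESIGN", paste0(
      "condition fails validation:\n",
      paste0("  [", v$code, "] ", v$message, collapse = "\n")))
  }
  m <- length(model$measure_labels)
  fac <- psd_factor(model$correlations)
  z <- matrix(stats::rnorm(cond$n * m), nrow = cond$n, ncol = m)
  x <- z %*% fac
  x <- sweep(x, 2L, model$sds, `*`)
  x <- sweep(x, 2L, model$means, `+`)
  stats::setNames(as.data.frame(x), model$measure_labels)
}

#' Simulate one direct replication and evaluate the criterion
#'
#' Draws one fresh sample per condition, runs every test in the criterion
#' on it through [two_sample_t()] / [paired_t()], and reports whether the
#' conjunction of required outcomes was met. This is the single-shot
#' reference path; [estimate_success()] runs the same model vectorised.
#'
#' @inheritParams estimate_success
#' @return A list with `results` (data frame: one row per test with
#'   statistic, df, p value, direction, significance and whether the
#'   requirement was met) and `success` (logical: all requirements met).
#' @export
simulate_once <- function(design, criterion, variant = c("pooled", "welch"),
                          enforce_direction = TRUE) {
  variant <- match.arg(variant)
  assert_valid(design, criterion)
  samples <- lapply(design$conditions, sample_condition)
  names(samples) <- vapply(design$conditions, `[[`, "", "label")
  rows <- lapply(criterion$tests, function(ts) {
    res <- if (ts$kind == "between") {
      two_sample_t(samples[[ts$condition]][[ts$measure]],
                   samples[[ts$condition_b]][[ts$measure]],
                   variant = variant, alpha = ts$alpha, test_id = ts$test_id)
    } else {
      paired_t(samples[[ts$condition]][[ts$measure]] -
                 samples[[ts$condition]][[ts$measure_b]],
               alpha = ts$alpha, test_id = ts$test_id)
    }
    data.frame(test_id = res$test_id, statistic = res$statistic, df = res$df,
               p_value = res$p_value, direction = res$direction,
               significant = res$significant,
               met = meets_requirement(res, ts, enforce_direction),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(results = results, success = all(results$met))
}

# Which per-replication moments does the criterion need from each
# condition? Between tests need (mean, var) of single measure columns;
# within tests need (mean, var) of a difference of two columns.
required_moments <- function(design, criterion) {
  conds <- vapply(design$conditions, `[[`, "", "label")
  need <- stats::setNames(
    rep(list(list(measures = integer(), pairs = list())), length(conds)),
    conds)
  for (ts in criterion$tests) {
    mi <- resolve_measure(design, ts$measure)
    if (ts$kind == "between") {
      for (cl in c(ts$condition, ts$condition_b)) {
        need[[cl]]$measures <- union(need[[cl]]$measures, mi)
      }
    } else {
      mj <- resolve_measure(design, ts$measure_b)
      key <- paste(mi, mj, sep = "-")
      need[[ts$condition]]$pairs[[key]] <- c(mi, mj)
    }
  }
  need
}

# Per-replication means and variances for one condition across all reps,
# drawn in chunks to bound memory at large n * reps.
condition_moments <- function(cond, need, reps, chunk_target = 4e6) {
  model <- cond$model
  n <- cond$n
  m <- length(model$measure_labels)
  fac <- psd_factor(model$correlations)
  scale_fac <- fac * rep(model$sds, each = m)  # column j scaled by sds[j]
  out <- list(
    mean = lapply(stats::setNames(nm = as.character(need$measures)),
                  function(...) numeric(reps)),
    var = lapply(stats::setNames(nm = as.character(need$measures)),
                 function(...) numeric(reps)),
    dmean = lapply(need$pairs, function(...) numeric(reps)),
    dvar = lapply(need$pairs, function(...) numeric(reps))
  )
  chunk <- max(1L, min(reps, as.integer(chunk_target %/% (n * m))))
  done <- 0L
  while (done < reps) {
    r <- min(chunk, reps - done)
    idx <- seq.int(done + 1L, done + r)
    z <- matrix(stats::rnorm(r * n * m), nrow = r * n, ncol = m)
    x <- z %*% scale_fac
    cols <- lapply(seq_len(m), function(j) {
      matrix(x[, j] + model$means[j], nrow = n, ncol = r)
    })
    for (mi in need$measures) {
      cm <- cols[[mi]]
      mu <- .colMeans(cm, n, r)
      out$mean[[as.character(mi)]][idx] <- mu
      out$var[[as.character(mi)]][idx] <-
        (colSums(cm * cm) - n * mu * mu) / (n - 1)
    }
    for (key in names(need$pairs)) {
      pr <- need$pairs[[key]]
      dm <- cols[[pr[1L]]] - cols[[pr[2L]]]
      mu <- .colMeans(dm, n, r)
      out$dmean[[key]][idx] <- mu
      out$dvar[[key]][idx] <- (colSums(dm * dm) - n * mu * mu) / (n - 1)
    }
    done <- done + r
  }
  out
}

# Vectorised two-sided p values and requirement classification for one
# test across all replications.
evaluate_test_vec <- function(ts, design, moments, variant,
                              enforce_direction) {
  mi <- resolve_measure(design, ts$measure)
  if (ts$kind == "between") {
    a <- moments[[ts$condition]]
    b <- moments[[ts$condition_b]]
    n1 <- design$conditions[[resolve_condition(design, ts$condition)]]$n
    n2 <- design$conditions[[resolve_condition(design, ts$condition_b)]]$n
    key <- as.character(mi)
    delta <- a$mean[[key]] - b$mean[[key]]
    v1 <- a$var[[key]]; v2 <- b$var[[key]]
    if (variant == "pooled") {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      if (any(sp2 <= 0)) {
        tg_stop("DEGENERATE_SAMPLE", sprintf(
          "test '%s': zero pooled variance in a replication (degenerate model)",
          ts$test_id))
      }
      tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se2 <- v1 / n1 + v2 / n2
      if (any(se2 <= 0)) {
        tg_stop("DEGENERATE_SAMPLE", sprintf(
          "test '%s': zero variance in a replication (degenerate model)",
          ts$test_id))
      }
      tstat <- delta / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
  } else {
    mj <- resolve_measure(design, ts$measure_b)
    key <- paste(mi, mj, sep = "-")
    mom <- moments[[ts$condition]]
    n <- design$conditions[[resolve_condition(design, ts$condition)]]$n
    delta <- mom$dmean[[key]]
    vd <- mom$dvar[[key]]
    if (any(vd <= 0)) {
      tg_stop("DEGENERATE_SAMPLE", sprintf(
        "test '%s': zero variance of paired differences in a replication",
        ts$test_id))
    }
    tstat <- delta / sqrt(vd / n)
    df <- n - 1
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  sig <- p < ts$alpha
  if (ts$required == "nonsignificant") {
    !sig
  } else if (enforce_direction) {
    want_pos <- identical(ts$expected_sign, "positive")
    sig & (if (want_pos) delta > 0 else delta < 0)
  } else {
    sig
  }
}

#' Estimate the joint success probability of a study by simulation
#'
#' Draws `reps` simulated direct replications of `design` (each condition
#' sampled afresh from its multivariate normal population model), runs the
#' criterion's full battery of tests on every replication, and estimates
#' the probability that *all* requirements are met simultaneously, along
#' with each test's marginal success rate. This joint probability is the
#' quantity the Test for Excess Success is built on: tests sharing samples
#' are dependent, so the joint probability is not the product of the
#' marginals and has to be simulated.
#'
#' @param design A [study_design()].
#' @param criterion A [success_criterion()] resolving against `design`.
#' @param reps Number of simulated replications (default 100,000; at least
#'   100 for the Monte-Carlo standard error to be meaningful).
#' @param seed Integer seed; the estimate is fully reproducible from it.
#' @param variant Two-sample test variant, `"pooled"` or `"welch"`.
#' @param enforce_direction Count a required-significant test as met only
#'   when the observed sign matches `expected_sign` (default `TRUE`).
#'
#' @return A `success_estimate` with fields `p_hat` (joint success
#'   probability), `reps`, `mc_se` (`sqrt(p_hat (1 - p_hat) / reps)`),
#'   `per_test_rates` (named marginal rates), and `seed`. The invariant
#'   `p_hat <= min(per_test_rates)` holds exactly since marginals are
#'   counted on the same replications.
#' @examples
#' d <- study_design("null", list(
#'   condition_spec("a", 15, measure_model("m", 0, 1)),
#'   condition_spec("b", 15, measure_model("m", 0, 1))))
#' crit <- success_criterion(test_spec(
#'   "t1", "between", condition = "a", condition_b = "b", measure = "m",
#'   required = "nonsignificant"))
#' estimate_success(d, crit, reps = 1000, seed = 1)  # p_hat near 0.95
#' @export
estimate_success <- function(design, criterion, reps = 1e5, seed = 1L,
                             variant = c("pooled", "welch"),
                             enforce_direction = TRUE) {
  variant <- match.arg(variant)
  if (!is_scalar_number(reps) || reps < 100) {
    tg_stop("INSUFFICIENT_REPS",
            "reps must be at least 100 for a meaningful estimate")
  }
  reps <- as.integer(reps)
  assert_valid(design, criterion)
  need <- required_moments(design, criterion)
  # only conditions some test actually references consume random draws
  used <- names(need)[vapply(need, function(x) {
    length(x$measures) + length(x$pairs) > 0L
  }, NA)]
  moments <- with_seed_mt(seed, {
    lapply(stats::setNames(nm = used), function(cl) {
      ci <- resolve_condition(design, cl)
      condition_moments(design$conditions[[ci]], need[[cl]], reps)
    })
  })
  met <- lapply(criterion$tests, evaluate_test_vec, design = design,
                moments = moments, variant = variant,
                enforce_direction = enforce_direction)
  ids <- vapply(criterion$tests, `[[`, "", "test_id")
  success <- Reduce(`&`, met)
  p_hat <- mean(success)
  structure(
    list(p_hat = p_hat, reps = reps,
         mc_se = sqrt(p_hat * (1 - p_hat) / reps),
         per_test_rates = stats::setNames(vapply(met, mean, 0), ids),
         requirements = stats::setNames(
           vapply(criterion$tests, `[[`, "", "required"), ids),
         seed = as.integer(seed), variant = variant,
         enforce_direction = enforce_direction,
         study_label = design$study_label),
    class = "success_estimate"
  )
}

#' @export
print.success_estimate <- function(x, ...) {
  cat(sprintf("<success_estimate> %s: p_hat = %.3f (mc_se = %.4f, reps = %d, seed = %d)\n",
              x$study_label, x$p_hat, x$mc_se, x$reps, x$seed))
  cat("  per-test marginal success rates:\n")
  for (id in names(x$per_test_rates)) {
    cat(sprintf("    %-14s %.3f\n", id, x$per_test_rates[[id]]))
  }
  invisible(x)
}
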