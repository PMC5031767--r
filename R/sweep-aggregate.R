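# Success-versus-sample-size curves with ceiling detection, and the
# multi-study product aggregation that yields the excess-success flag.

# Re-instantiate a design with every condition's n replaced (equal
# allocation across conditions, as in a planned replication).
with_sample_size <- function(design, n) {
  design$conditions <- lapply(design$conditions, function(cond) {
    cond$n <- as.integer(n)
    cond
  })
  design
}

#' Success probability as a function of per-condition sample size
#'
#' For each grid value, rebuilds the design with that sample size in every
#' condition (equal allocation) and estimates the joint success
#' probability by simulation, together with each test's marginal success
#' curve. When a criterion mixes significance and non-significance
#' requirements the joint curve typically rises, peaks at an intermediate
#' sample size, and then falls — the ceiling phenomenon: the small true
#' effects behind the "null" tests eventually reach significance, so no
#' sample size can make full success certain.
#'
#' @inheritParams estimate_success
#' @param design_template A [study_design()] whose condition sample sizes
#'   are overridden at each grid point.
#' @param n_grid Strictly increasing integer vector of per-condition
#'   sample sizes, minimum 2. Default `seq(5, 200, by = 5)`.
#' @param reps_per_point Simulated replications per grid point (default
#'   10,000).
#' @param seed Master seed; each grid point runs on an independent
#'   substream derived from it.
#'
#' @return A `sweep_result` with `n_grid`, `estimates` (list of
#'   `success_estimate`), `curve` (data frame: `n`, `p_hat`, `mc_se`, one
#'   column per test's marginal rate), and the optimum `n_star` / `p_max`.
#' @seealso [find_optimum()], [aggregate_product()]
#' @export
success_curve <- function(design_template, criterion,
                          n_grid = seq(5L, 200L, by = 5L),
                          reps_per_point = 1e4, seed = 1L,
                          variant = c("pooled", "welch"),
                          enforce_direction = TRUE) {
  variant <- match.arg(variant)
  n_grid <- as.integer(n_grid)
  if (length(n_grid) < 1L || any(n_grid < 2L) ||
      any(diff(n_grid) <= 0L)) {
    tg_stop("BAD_GRID", "n_grid must be strictly increasing with min >= 2")
  }
  assert_valid(design_template, criterion)
  seeds <- substream_seeds(seed, length(n_grid))
  estimates <- vector("list", length(n_grid))
  for (i in seq_along(n_grid)) {
    estimates[[i]] <- estimate_success(
      with_sample_size(design_template, n_grid[i]), criterion,
      reps = reps_per_point, seed = seeds[i], variant = variant,
      enforce_direction = enforce_direction)
  }
  marg <- do.call(rbind, lapply(estimates, function(e) e$per_test_rates))
  curve <- data.frame(
    n = n_grid,
    p_hat = vapply(estimates, `[[`, 0, "p_hat"),
    mc_se = vapply(estimates, `[[`, 0, "mc_se")
  )
  curve <- cbind(curve, as.data.frame(marg))
  i_star <- which.max(curve$p_hat)  # ties -> smallest n (first index)
  structure(
    list(n_grid = n_grid, estimates = estimates, curve = curve,
         n_star = n_grid[i_star], p_max = curve$p_hat[i_star],
         seed = as.integer(seed)),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d grid points, n in [%d, %d]: max p_hat = %.3f at n = %d\n",
    length(x$n_grid), min(x$n_grid), max(x$n_grid), x$p_max, x$n_star))
  invisible(x)
}

#' Locate the attainable ceiling of a success curve
#'
#' @param sweep A `sweep_result` from [success_curve()].
#' @return List with `n_star` (grid value maximising the joint success
#'   probability; smallest such n on ties — the cheaper design) and
#'   `p_max`.
#' @export
find_optimum <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  list(n_star = sweep$n_star, p_max = sweep$p_max)
}

#' Combine independent studies into the excess-success diagnostic
#'
#' Since the studies rest on independent samples, the probability that a
#' direct replication of the whole set succeeds everywhere is the product
#' of the per-study success probabilities. A product far below any
#' plausible chance level — despite every reported study having succeeded
#' — is the "too good to be true" signal: it suggests selective reporting,
#' flexible analysis, or claims fitted to sampling noise.
#'
#' @param per_study Named numeric vector (or list) of per-study success
#'   probabilities in \[0, 1\].
#' @param threshold Flagging cutoff in (0, 1); `excess_flag` is
#'   `p_tes < threshold`. The default 0.1 follows the convention of the
#'   excess-success literature and is always reported alongside the
#'   product.
#'
#' @return A `multi_study_result` with `per_study`, `p_tes` (the product),
#'   `threshold` and `excess_flag`.
#' @examples
#' aggregate_product(c(s1 = 0.163, s2 = 0.380, s3 = 0.575,
#'                     s4 = 0.450, s5 = 0.212))  # p_tes ~ 0.003
#' @export
aggregate_product <- function(per_study, threshold = 0.1) {
  per_study <- unlist(per_study)
  if (length(per_study) < 1L) {
    tg_stop("OUT_OF_RANGE", "at least one study is required")
  }
  if (any(!is.finite(per_study)) || any(per_study < 0) ||
      any(per_study > 1)) {
    tg_stop("OUT_OF_RANGE", "per-study probabilities must lie in [0, 1]")
  }
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    tg_stop("OUT_OF_RANGE", "threshold must lie in (0, 1)")
  }
  if (is.null(names(per_study))) {
    names(per_study) <- paste0("study", seq_along(per_study))
  }
  p_tes <- prod(per_study)
  structure(
    list(per_study = per_study, p_tes = p_tes, threshold = threshold,
         excess_flag = p_tes < threshold),
    class = "multi_study_result"
  )
}

#' @export
print.multi_study_result <- function(x, ...) {
  cat("<multi_study_result>\n")
  for (s in names(x$per_study)) {
    cat(sprintf("  %-14s %.3f\n", s, x$per_study[[s]]))
  }
  cat(sprintf("  p_tes = %.3f (threshold %.2f): %s\n", x$p_tes, x$threshold,
              if (x$excess_flag) "EXCESS SUCCESS — too good to be true"
              else "not flagged"))
  invisible(x)
}
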