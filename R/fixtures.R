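# Synthetic designs and criteria: random but always-valid fixtures for
# testing every other module without external data, plus the structural
# template of the three-condition, two-measure priming study whose seven
# tests motivate the package.

#' Configuration for the random design generator
#'
#' @param seed Integer seed; the generator is deterministic given it.
#' @param n_conditions Number of between-subject conditions (>= 1; at
#'   least 2 unless `n_measures >= 2`, otherwise no test can be formed).
#' @param n_measures Number of within-subject measures per participant.
#' @param effect_range Interval of standardized mean differences from
#'   which true effects are drawn (magnitudes; signs are randomised).
#' @param corr_range Interval within (-1, 1) bounding the magnitude of
#'   generated within-subject correlations.
#' @param n_range Integer interval of per-condition sample sizes (min 2).
#' @param mix Proportion of tests carrying a significance requirement (the
#'   rest require non-significance).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_conditions = 3L, n_measures = 2L,
                           effect_range = c(0.2, 1.2),
                           corr_range = c(0.1, 0.7),
                           n_range = c(8L, 40L), mix = 0.7) {
  cfg <- list(seed = as.integer(seed), n_conditions = as.integer(n_conditions),
              n_measures = as.integer(n_measures),
              effect_range = as.numeric(effect_range),
              corr_range = as.numeric(corr_range),
              n_range = as.integer(n_range), mix = as.numeric(mix))
  if (cfg$n_conditions < 1L || cfg$n_measures < 1L) {
    tg_stop("BAD_CONFIG", "need at least one condition and one measure")
  }
  if (cfg$n_conditions < 2L && cfg$n_measures < 2L) {
    tg_stop("BAD_CONFIG",
            "no test can be formed from one condition and one measure")
  }
  if (length(cfg$n_range) != 2L || cfg$n_range[1L] < 2L ||
      diff(cfg$n_range) < 0) {
    tg_stop("BAD_CONFIG", "n_range must be an integer interval with min >= 2")
  }
  if (any(abs(cfg$corr_range) >= 1) || diff(cfg$corr_range) < 0) {
    tg_stop("BAD_CONFIG", "corr_range must lie within (-1, 1)")
  }
  if (diff(cfg$effect_range) < 0 || cfg$mix < 0 || cfg$mix > 1) {
    tg_stop("BAD_CONFIG", "bad effect_range or mix")
  }
  structure(cfg, class = "fixture_config")
}

# Random correlation matrix, PSD by construction: cov2cor of a random
# two-factor loading structure plus diagonal noise, then shrunk toward
# the identity so off-diagonals respect the configured magnitude bound
# (a convex combination with I preserves PSD).
random_correlation <- function(m, corr_range) {
  if (m == 1L) return(matrix(1, 1, 1))
  if (m == 2L) {
    rho <- stats::runif(1, corr_range[1L], corr_range[2L])
    return(matrix(c(1, rho, rho, 1), 2L))
  }
  loadings <- matrix(stats::runif(m * 2L, -1, 1), m, 2L)
  w <- loadings %*% t(loadings) + diag(stats::runif(m, 0.2, 1), m)
  r0 <- stats::cov2cor(w)
  max_off <- max(abs(r0[upper.tri(r0)]))
  cap <- max(abs(corr_range))
  s <- if (max_off > 0) min(1, cap / max_off) else 1
  diag(1, m) + s * (r0 - diag(1, m))
}

#' Generate a random valid design and matching criterion
#'
#' Produces a study design whose population effects, correlations and
#' sample sizes are drawn from the configured ranges, together with a
#' success criterion whose operands all resolve against the design. Every
#' output passes [validate_design()] by construction; significance
#' requirements carry the expected sign of the true population effect, so
#' a requirement is attainable rather than contradictory.
#'
#' @param cfg A [fixture_config()].
#' @return List with elements `design` and `criterion`.
#' @examples
#' fx <- make_random_design(fixture_config(seed = 42))
#' nrow(validate_design(fx$design, fx$criterion))  # 0
#' @export
make_random_design <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed_mt(cfg$seed, {
    m <- cfg$n_measures
    k <- cfg$n_conditions
    measures <- paste0("m", seq_len(m))
    # one population SD per measure, shared by all conditions: generated
    # designs satisfy the variance-homogeneity assumption of the pooled
    # t tests they are analysed with (heteroscedastic designs can still
    # be written by hand)
    sds <- stats::runif(m, 0.8, 1.2)
    conds <- lapply(seq_len(k), function(i) {
      # condition 1 is the baseline; others shift each measure by a
      # standardized effect of random sign from effect_range
      means <- if (i == 1L) rep(0, m) else {
        stats::runif(m, cfg$effect_range[1L], cfg$effect_range[2L]) *
          sample(c(-1, 1), m, replace = TRUE) * sds
      }
      condition_spec(
        paste0("c", i),
        sample(seq.int(cfg$n_range[1L], cfg$n_range[2L]), 1L),
        measure_model(measures, means, sds,
                      random_correlation(m, cfg$corr_range)))
    })
    design <- study_design(paste0("fixture_seed", cfg$seed), conds)

    tests <- list()
    add_test <- function(ts) tests[[length(tests) + 1L]] <<- ts
    make_required <- function() {
      if (stats::runif(1) < cfg$mix) "significant" else "nonsignificant"
    }
    spec_for <- function(id, kind, ca, cb = NULL, ma, mb = NULL) {
      req <- make_required()
      sign <- NULL
      if (req == "significant") {
        probe <- test_spec(id, kind, condition = ca, condition_b = cb,
                           measure = ma, measure_b = mb,
                           required = "significant",
                           expected_sign = "positive")
        eff <- design_effect(design, probe)
        true_delta <- if (kind == "between") eff$d else eff$dz
        sign <- if (true_delta >= 0) "positive" else "negative"
      }
      test_spec(id, kind, condition = ca, condition_b = cb,
                measure = ma, measure_b = mb, required = req,
                expected_sign = sign)
    }
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) {
        ma <- sample(measures, 1L)
        add_test(spec_for(paste0("between_", i), "between",
                          ca = paste0("c", i + 1L), cb = paste0("c", i),
                          ma = ma))
      }
    }
    if (m >= 2L) {
      for (i in seq_len(k)) {
        if (i > 1L && stats::runif(1) > 0.5) next
        pair <- sample(measures, 2L)
        add_test(spec_for(paste0("within_", i), "within",
                          ca = paste0("c", i), ma = pair[1L], mb = pair[2L]))
      }
    }
    list(design = design, criterion = success_criterion(tests))
  })
}

#' Structural template of the three-condition priming study
#'
#' Builds the design and seven-test success criterion of the classic
#' subliminal-priming detection study: three between-subject prime
#' conditions (white prime, no prime, black prime; n = 13, 12 and 14) and
#' two correlated within-subject measures, frames-to-detection for
#' crime-relevant and crime-irrelevant objects. The criterion requires
#' five significant outcomes — white vs black, black vs no-prime and
#' white vs no-prime on the crime-relevant measure, plus the within-
#' subject relevant-vs-irrelevant contrast in both prime conditions — and
#' two non-significant outcomes (black vs no-prime and white vs no-prime
#' on the crime-irrelevant measure). Expected signs encode the claimed
#' tuning: black priming speeds detection of crime-relevant objects
#' (fewer frames), white priming slows it.
#'
#' The template deliberately ships with **no default numeric parameters**:
#' the original article prints no usable means, SDs or correlations, so
#' population models must be supplied explicitly (or via
#' [load_parameters()]) rather than silently defaulted.
#'
#' @param params Named list of three [measure_model()]s over the measures
#'   `crime_relevant`, `crime_irrelevant`, keyed `white_prime`,
#'   `no_prime`, `black_prime`.
#' @param alpha Significance level applied to all seven tests.
#' @return List with elements `design` and `criterion`.
#' @export
study1_template <- function(params, alpha = 0.05) {
  keys <- c("white_prime", "no_prime", "black_prime")
  if (!is.list(params) || !all(keys %in% names(params))) {
    tg_stop("BAD_CONFIG", paste(
      "params must be a named list of measure_models keyed",
      paste(keys, collapse = ", ")))
  }
  measures <- c("crime_relevant", "crime_irrelevant")
  for (key in keys) {
    if (!identical(params[[key]]$measure_labels, measures)) {
      tg_stop("BAD_CONFIG", sprintf(
        "params$%s must model measures %s (in order)", key,
        paste(measures, collapse = ", ")))
    }
  }
  ns <- c(white_prime = 13L, no_prime = 12L, black_prime = 14L)
  design <- study_design("study1", lapply(keys, function(key) {
    condition_spec(key, ns[[key]], params[[key]])
  }))
  bt <- function(id, a, b, meas, req, sign = NULL) {
    test_spec(id, "between", condition = a, condition_b = b, measure = meas,
              required = req, expected_sign = sign, alpha = alpha)
  }
  wt <- function(id, cond, sign) {
    test_spec(id, "within", condition = cond, measure = "crime_relevant",
              measure_b = "crime_irrelevant", required = "significant",
              expected_sign = sign, alpha = alpha)
  }
  criterion <- success_criterion(list(
    # white-primed detect crime-relevant objects slower than black-primed
    bt("rel_white_vs_black", "white_prime", "black_prime", "crime_relevant",
       "significant", "positive"),
    # black priming speeds crime-relevant detection vs no prime
    bt("rel_black_vs_none", "black_prime", "no_prime", "crime_relevant",
       "significant", "negative"),
    # black-primed: crime-relevant faster than crime-irrelevant
    wt("within_black", "black_prime", "negative"),
    # white priming slows crime-relevant detection vs no prime
    bt("rel_white_vs_none", "white_prime", "no_prime", "crime_relevant",
       "significant", "positive"),
    # white-primed: crime-relevant slower than crime-irrelevant
    wt("within_white", "white_prime", "positive"),
    # priming is specific to crime-relevant objects: no effect on the
    # irrelevant measure
    bt("irr_black_vs_none", "black_prime", "no_prime", "crime_irrelevant",
       "nonsignificant"),
    bt("irr_white_vs_none", "white_prime", "no_prime", "crime_irrelevant",
       "nonsignificant")
  ))
  list(design = design, criterion = criterion)
}

CORR_MARKER <- "# correlations"

parse_error <- function(path, msg) {
  tg_stop("PARSE_ERROR", sprintf("%s: %s", path, msg))
}

#' Read condition-level population parameters from a CSV file
#'
#' The file holds a moments block with columns
#' `condition,measure,mean,sd`, optionally followed by a line
#' `# correlations` and a correlation block with columns
#' `condition,measure_a,measure_b,correlation`. Unlisted correlations
#' default to 0. Measure order follows first appearance in the moments
#' block and must be consistent across conditions.
#'
#' @param path Path to the parameter file.
#' @return Named list of [measure_model()]s, keyed by condition label.
#' @seealso [write_parameters()] for the inverse; [study1_template()] for
#'   the design the parameters typically feed.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) parse_error(path, "file not found")
  lines <- readLines(path, warn = FALSE)
  marker <- which(trimws(lines) == CORR_MARKER)
  if (length(marker) > 1L) parse_error(path, "multiple correlation blocks")
  mom_lines <- if (length(marker)) lines[seq_len(marker - 1L)] else lines
  cor_lines <- if (length(marker)) lines[-seq_len(marker)] else character()

  mom <- tryCatch(
    read.csv(text = paste(mom_lines, collapse = "\n"),
             stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) parse_error(path, conditionMessage(e)))
  need <- c("condition", "measure", "mean", "sd")
  if (!all(need %in% names(mom))) {
    parse_error(path, sprintf("moments block must have columns %s",
                              paste(need, collapse = ", ")))
  }
  if (nrow(mom) == 0L) parse_error(path, "no parameter rows")
  if (!is.numeric(mom$mean) || !is.numeric(mom$sd) ||
      anyNA(mom$mean) || anyNA(mom$sd)) {
    parse_error(path, "mean and sd must be numeric and complete")
  }
  measures <- unique(mom$measure)

  cors <- NULL
  if (length(cor_lines) && any(nzchar(trimws(cor_lines)))) {
    cors <- tryCatch(
      read.csv(text = paste(cor_lines, collapse = "\n"),
               stringsAsFactors = FALSE, strip.white = TRUE),
      error = function(e) parse_error(path, conditionMessage(e)))
    cneed <- c("condition", "measure_a", "measure_b", "correlation")
    if (!all(cneed %in% names(cors))) {
      parse_error(path, sprintf("correlation block must have columns %s",
                                paste(cneed, collapse = ", ")))
    }
    if (!is.numeric(cors$correlation) || anyNA(cors$correlation)) {
      parse_error(path, "correlations must be numeric and complete")
    }
  }

  models <- list()
  for (cl in unique(mom$condition)) {
    block <- mom[mom$condition == cl, , drop = FALSE]
    if (!identical(block$measure, measures)) {
      parse_error(path, sprintf(
        "condition '%s' must list measures %s in order", cl,
        paste(measures, collapse = ", ")))
    }
    m <- length(measures)
    cm <- diag(1, m)
    if (!is.null(cors)) {
      cb <- cors[cors$condition == cl, , drop = FALSE]
      for (i in seq_len(nrow(cb))) {
        ia <- match(cb$measure_a[i], measures)
        ib <- match(cb$measure_b[i], measures)
        if (is.na(ia) || is.na(ib)) {
          parse_error(path, sprintf(
            "condition '%s': correlation names unknown measure", cl))
        }
        cm[ia, ib] <- cm[ib, ia] <- cb$correlation[i]
      }
    }
    models[[cl]] <- measure_model(measures, block$mean, block$sd, cm)
  }
  models
}

#' Write condition-level population parameters to a CSV file
#'
#' Inverse of [load_parameters()]: writes the moments block and, when any
#' model has correlated measures, the correlation block.
#'
#' @param models Named list of [measure_model()]s keyed by condition.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(models, path) {
  mom <- do.call(rbind, lapply(names(models), function(cl) {
    mm <- models[[cl]]
    data.frame(condition = cl, measure = mm$measure_labels,
               mean = mm$means, sd = mm$sds, stringsAsFactors = FALSE)
  }))
  cons <- do.call(rbind, lapply(names(models), function(cl) {
    mm <- models[[cl]]
    m <- length(mm$measure_labels)
    if (m < 2L) return(NULL)
    ut <- which(upper.tri(mm$correlations), arr.ind = TRUE)
    data.frame(condition = cl,
               measure_a = mm$measure_labels[ut[, 1L]],
               measure_b = mm$measure_labels[ut[, 2L]],
               correlation = mm$correlations[ut],
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(mom, con, row.names = FALSE, quote = FALSE)
  if (!is.null(cons) && nrow(cons) > 0L) {
    writeLines(CORR_MARKER, con)
    write.csv(cons, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
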