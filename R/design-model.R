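# Declarative representation of an experiment's population model and the
# success criterion that operationalises its claims.

#' Population model of the within-subject measures in one condition
#'
#' Bundles the population means, standard deviations and correlation matrix
#' of the correlated within-subject measures recorded for every participant
#' in one experimental condition. Simulated participants are drawn from the
#' multivariate normal distribution this model defines.
#'
#' @param measure_labels Character vector naming the measures (e.g.
#'   `"crime_relevant"`, `"crime_irrelevant"`), in a fixed order shared by
#'   all conditions of a design.
#' @param means Numeric vector of population means, one per measure, in
#'   response units (e.g. frames to detection).
#' @param sds Numeric vector of population standard deviations, one per
#'   measure; all must be strictly positive.
#' @param correlations Square symmetric correlation matrix among the
#'   measures, unit diagonal, positive semidefinite. Defaults to the
#'   identity (uncorrelated measures).
#'
#' @return An object of class `measure_model`.
#' @examples
#' measure_model(c("relevant", "irrelevant"), means = c(24, 26),
#'               sds = c(5, 5), correlations = matrix(c(1, .4, .4, 1), 2))
#' @export
measure_model <- function(measure_labels, means, sds, correlations = NULL) {
  measure_labels <- as.character(measure_labels)
  if (is.null(correlations)) {
    correlations <- diag(length(measure_labels))
  }
  correlations <- as.matrix(correlations)
  structure(
    list(measure_labels = measure_labels,
         means = as.numeric(means),
         sds = as.numeric(sds),
         correlations = unname(correlations)),
    class = "measure_model"
  )
}

#' One experimental condition: label, sample size, population model
#'
#' @param label Unique condition identifier (e.g. `"white_prime"`).
#' @param n Integer sample size, at least 2 (a t test needs two
#'   observations per group).
#' @param model A [measure_model()] for this condition's measures.
#'
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(label, n, model) {
  structure(
    list(label = as.character(label), n = as.integer(n), model = model),
    class = "condition_spec"
  )
}

#' A full study design: conditions sharing one set of measures
#'
#' @param study_label Identifier for the study.
#' @param conditions List of [condition_spec()] objects; all must expose
#'   identical measure labels in identical order.
#'
#' @return An object of class `study_design`.
#' @seealso [validate_design()] for the full invariant check,
#'   [estimate_success()] to simulate it.
#' @export
study_design <- function(study_label, conditions) {
  if (inherits(conditions, "condition_spec")) conditions <- list(conditions)
  structure(
    list(study_label = as.character(study_label), conditions = conditions),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$study_label, "\n", sep = "")
  for (cond in x$conditions) {
    cat(sprintf("  %-14s n = %-4d measures: %s\n", cond$label, cond$n,
                paste(cond$model$measure_labels, collapse = ", ")))
  }
  invisible(x)
}

#' Specify one hypothesis test and its required outcome
#'
#' A test is either a between-condition two-sample t test on one measure,
#' or a within-condition paired t test between two measures. The required
#' outcome is what the original article's claims need from it: a
#' significant result with a specific sign, or a non-significant result.
#'
#' @param test_id Unique identifier for the test.
#' @param kind `"between"` (two-sample) or `"within"` (paired).
#' @param condition,condition_b For `kind = "between"`: the two condition
#'   labels compared (difference taken as `condition` minus
#'   `condition_b`). For `kind = "within"`: `condition` names the single
#'   condition and `condition_b` must be `NULL`.
#' @param measure,measure_b For `kind = "between"`: `measure` names the
#'   measure compared and `measure_b` must be `NULL`. For
#'   `kind = "within"`: the two measures whose paired difference
#'   (`measure` minus `measure_b`) is tested.
#' @param required `"significant"` (significant in the expected direction)
#'   or `"nonsignificant"`.
#' @param expected_sign `"positive"`, `"negative"`, or `"none"` (only
#'   valid, and the default, when `required = "nonsignificant"`). The sign
#'   refers to the mean difference in the operand order above.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#'
#' @return An object of class `test_spec`.
#' @examples
#' test_spec("rel_wb", "between", condition = "white_prime",
#'           condition_b = "black_prime", measure = "crime_relevant",
#'           required = "significant", expected_sign = "positive")
#' @export
test_spec <- function(test_id, kind = c("between", "within"),
                      condition, condition_b = NULL,
                      measure, measure_b = NULL,
                      required = c("significant", "nonsignificant"),
                      expected_sign = NULL, alpha = 0.05) {
  kind <- match.arg(kind)
  required <- match.arg(required)
  if (is.null(expected_sign)) {
    expected_sign <- if (required == "nonsignificant") "none" else NA_character_
  }
  structure(
    list(test_id = as.character(test_id), kind = kind,
         condition = as.character(condition),
         condition_b = if (!is.null(condition_b)) as.character(condition_b),
         measure = as.character(measure),
         measure_b = if (!is.null(measure_b)) as.character(measure_b),
         required = required, expected_sign = as.character(expected_sign),
         alpha = alpha),
    class = "test_spec"
  )
}

#' The conjunction of required test outcomes defining full success
#'
#' A replication counts as fully successful only when every test in the
#' criterion meets its requirement — the same all-or-nothing standard the
#' original article's claims impose.
#'
#' @param tests List of [test_spec()] objects (at least one), with unique
#'   `test_id`s.
#' @return An object of class `success_criterion`.
#' @export
success_criterion <- function(tests) {
  if (inherits(tests, "test_spec")) tests <- list(tests)
  if (length(tests) < 1L) {
    tg_stop("EMPTY_CRITERION", "a success criterion needs at least one test")
  }
  structure(list(tests = tests), class = "success_criterion")
}

#' @export
print.success_criterion <- function(x, ...) {
  cat("<success_criterion> ", length(x$tests), " tests (conjunction)\n",
      sep = "")
  for (ts in x$tests) {
    op <- if (ts$kind == "between") {
      sprintf("%s vs %s on %s", ts$condition, ts$condition_b, ts$measure)
    } else {
      sprintf("%s: %s vs %s (paired)", ts$condition, ts$measure, ts$measure_b)
    }
    req <- if (ts$required == "significant") {
      paste0("significant (", ts$expected_sign, ")")
    } else "non-significant"
    cat(sprintf("  %-12s %-9s %-40s -> %s\n", ts$test_id, ts$kind, op, req))
  }
  invisible(x)
}

violation <- function(code, message) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(code = character(), message = character(),
             stringsAsFactors = FALSE)
}

validate_measure_model <- function(model, where) {
  v <- no_violations()
  k <- length(model$measure_labels)
  if (length(model$means) != k || length(model$sds) != k) {
    v <- rbind(v, violation("MEASURE_LENGTH_MISMATCH", sprintf(
      "%s: labels/means/sds lengths differ (%d labels, %d means, %d sds)",
      where, k, length(model$means), length(model$sds))))
  }
  if (anyDuplicated(model$measure_labels)) {
    v <- rbind(v, violation("DUPLICATE_MEASURE_LABEL",
                            sprintf("%s: duplicated measure labels", where)))
  }
  if (any(!is.finite(model$sds)) || any(model$sds <= 0)) {
    v <- rbind(v, violation("NONPOSITIVE_SD", sprintf(
      "%s: all sds must be strictly positive", where)))
  }
  if (any(!is.finite(model$means))) {
    v <- rbind(v, violation("NONFINITE_MEAN",
                            sprintf("%s: means must be finite", where)))
  }
  cm <- model$correlations
  if (!is.matrix(cm) || nrow(cm) != k || ncol(cm) != k) {
    v <- rbind(v, violation("CORR_DIM_MISMATCH", sprintf(
      "%s: correlation matrix must be %d x %d", where, k, k)))
    return(v)  # remaining matrix checks meaningless
  }
  if (any(!is.finite(cm)) || any(abs(cm) > 1)) {
    v <- rbind(v, violation("CORR_OUT_OF_RANGE", sprintf(
      "%s: correlations must lie in [-1, 1]", where)))
  }
  if (any(abs(diag(cm) - 1) > 1e-12)) {
    v <- rbind(v, violation("CORR_DIAG_NOT_UNIT", sprintf(
      "%s: correlation matrix must have unit diagonal", where)))
  }
  if (any(abs(cm - t(cm)) > 1e-12)) {
    v <- rbind(v, violation("CORR_NOT_SYMMETRIC", sprintf(
      "%s: correlation matrix must be symmetric", where)))
  } else if (all(is.finite(cm))) {
    # PSD check only on a symmetric finite matrix; tolerance absorbs
    # round-trip float noise from config files, nothing larger — a matrix
    # failing it is rejected, never silently repaired.
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      v <- rbind(v, violation("CORR_NOT_PSD", sprintf(
        "%s: correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
        where, min(ev))))
    }
  }
  v
}

resolve_measure <- function(design, label) {
  match(label, design$conditions[[1L]]$model$measure_labels)
}

resolve_condition <- function(design, label) {
  match(label, vapply(design$conditions, `[[`, "", "label"))
}

validate_test_spec <- function(ts, design) {
  v <- no_violations()
  where <- sprintf("test '%s'", ts$test_id)
  if (!is_scalar_number(ts$alpha) || ts$alpha <= 0 || ts$alpha >= 1) {
    v <- rbind(v, violation("ALPHA_OUT_OF_RANGE",
                            sprintf("%s: alpha must be in (0, 1)", where)))
  }
  if (ts$required == "significant") {
    if (!isTRUE(ts$expected_sign %in% c("positive", "negative"))) {
      v <- rbind(v, violation("SIGN_REQUIRED", sprintf(
        "%s: a significance requirement needs expected_sign positive/negative",
        where)))
    }
  } else if (!identical(ts$expected_sign, "none")) {
    v <- rbind(v, violation("SIGN_FORBIDDEN", sprintf(
      "%s: a non-significance requirement takes expected_sign 'none'", where)))
  }
  conds <- c(ts$condition, ts$condition_b)
  for (cl in conds) {
    if (is.na(resolve_condition(design, cl))) {
      v <- rbind(v, violation("UNRESOLVED_OPERAND", sprintf(
        "%s: unknown condition '%s'", where, cl)))
    }
  }
  meas <- c(ts$measure, ts$measure_b)
  for (ml in meas) {
    if (is.na(resolve_measure(design, ml))) {
      v <- rbind(v, violation("UNRESOLVED_OPERAND", sprintf(
        "%s: unknown measure '%s'", where, ml)))
    }
  }
  if (ts$kind == "between") {
    if (is.null(ts$condition_b) || !is.null(ts$measure_b)) {
      v <- rbind(v, violation("OPERAND_ARITY", sprintf(
        "%s: a between test takes two conditions and one measure", where)))
    } else if (identical(ts$condition, ts$condition_b)) {
      v <- rbind(v, violation("OPERAND_ARITY", sprintf(
        "%s: a between test needs two distinct conditions", where)))
    }
  } else {
    if (!is.null(ts$condition_b) || is.null(ts$measure_b)) {
      v <- rbind(v, violation("OPERAND_ARITY", sprintf(
        "%s: a within test takes one condition and two measures", where)))
    } else if (identical(ts$measure, ts$measure_b)) {
      v <- rbind(v, violation("OPERAND_ARITY", sprintf(
        "%s: a within test needs two distinct measures", where)))
    }
  }
  v
}

#' Validate a study design against its success criterion
#'
#' Checks every structural invariant of the design (consistent measure
#' sets, positive SDs, well-formed positive-semidefinite correlation
#' matrices, sample sizes of at least 2) and of the criterion (unique test
#' ids, resolvable operands, coherent sign requirements). Violations are
#' returned, not thrown, so a caller can report all of them at once; an
#' empty result means the pair is simulable.
#'
#' @param design A [study_design()].
#' @param criterion A [success_criterion()], or `NULL` to validate the
#'   design alone.
#'
#' @return A data frame with columns `code` (machine-readable violation
#'   code) and `message`; zero rows iff valid.
#' @examples
#' d <- study_design("demo", list(
#'   condition_spec("a", 10, measure_model("m", 0, 1)),
#'   condition_spec("b", 10, measure_model("m", 1, 1))))
#' crit <- success_criterion(test_spec(
#'   "t1", "between", condition = "b", condition_b = "a", measure = "m",
#'   required = "significant", expected_sign = "positive"))
#' validate_design(d, crit)  # zero rows: valid
#' @export
validate_design <- function(design, criterion = NULL) {
  stopifnot(inherits(design, "study_design"))
  v <- no_violations()
  if (length(design$conditions) < 1L) {
    return(rbind(v, violation("NO_CONDITIONS",
                              "a design needs at least one condition")))
  }
  labels <- vapply(design$conditions, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    v <- rbind(v, violation("DUPLICATE_CONDITION_LABEL",
                            "condition labels must be unique"))
  }
  ref_measures <- design$conditions[[1L]]$model$measure_labels
  for (cond in design$conditions) {
    where <- sprintf("condition '%s'", cond$label)
    if (!is.numeric(cond$n) || length(cond$n) != 1L || is.na(cond$n) ||
        cond$n < 2) {
      v <- rbind(v, violation("N_TOO_SMALL", sprintf(
        "%s: sample size must be an integer >= 2", where)))
    }
    if (!identical(cond$model$measure_labels, ref_measures)) {
      v <- rbind(v, violation("MEASURE_SET_MISMATCH", sprintf(
        "%s: measure labels differ from the design's shared set", where)))
    }
    v <- rbind(v, validate_measure_model(cond$model, where))
  }
  if (!is.null(criterion)) {
    stopifnot(inherits(criterion, "success_criterion"))
    ids <- vapply(criterion$tests, `[[`, "", "test_id")
    if (anyDuplicated(ids)) {
      v <- rbind(v, violation("DUPLICATE_TEST_ID",
                              "test ids must be unique within a criterion"))
    }
    for (ts in criterion$tests) {
      v <- rbind(v, validate_test_spec(ts, design))
    }
  }
  v
}

# Throwing wrapper used by the simulation entry points.
assert_valid <- function(design, criterion = NULL) {
  v <- validate_design(design, criterion)
  if (nrow(v) > 0L) {
    tg_stop("INVALID_DESIGN", paste0(
      "invalid design/criterion:\n",
      paste0("  [", v$code, "] ", v$message, collapse = "\n")))
  }
  invisible(TRUE)
}
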