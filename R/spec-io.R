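# Declarative YAML study specifications and tabular/JSON result reports.
# YAML is the human-authored input format (diff-able, citable in
# meta-research reports); parsing is strict — unknown fields are errors,
# and the schema is versioned.

SPEC_VERSION <- 1L

check_fields <- function(x, allowed, required, where, path) {
  if (!is.list(x)) {
    tg_stop("PARSE_ERROR",
            sprintf("%s: %s must be a mapping", path, where))
  }
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    tg_stop("PARSE_ERROR", sprintf("%s: unknown field(s) %s in %s", path,
                                   paste0("'", extra, "'", collapse = ", "),
                                   where))
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    tg_stop("PARSE_ERROR", sprintf("%s: missing field(s) %s in %s", path,
                                   paste0("'", missing, "'", collapse = ", "),
                                   where))
  }
  invisible(TRUE)
}

parse_condition <- function(node, measures, path) {
  where <- sprintf("condition '%s'", node$label %||% "?")
  # the field is spelled sample_size (not n) because YAML 1.1 implicitly
  # types a bare key `n` as boolean false
  check_fields(node, c("label", "sample_size", "means", "sds",
                       "correlations"),
               c("label", "sample_size", "means", "sds"), where, path)
  cm <- if (is.null(node$correlations)) NULL else {
    do.call(rbind, lapply(node$correlations, as.numeric))
  }
  condition_spec(node$label, node$sample_size,
                 measure_model(measures, as.numeric(unlist(node$means)),
                               as.numeric(unlist(node$sds)), cm))
}

parse_test <- function(node, path) {
  where <- sprintf("test '%s'", node$id %||% "?")
  check_fields(node, c("id", "kind", "condition", "condition_b", "measure",
                       "measure_b", "required", "expected_sign", "alpha"),
               c("id", "kind", "condition", "measure", "required"),
               where, path)
  test_spec(node$id, node$kind, condition = node$condition,
            condition_b = node$condition_b, measure = node$measure,
            measure_b = node$measure_b, required = node$required,
            expected_sign = node$expected_sign,
            alpha = node$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_study <- function(node, path) {
  where <- sprintf("study '%s'", node$label %||% "?")
  check_fields(node, c("label", "measures", "conditions", "tests"),
               c("label", "measures", "conditions", "tests"), where, path)
  measures <- as.character(unlist(node$measures))
  design <- study_design(node$label,
                         lapply(node$conditions, parse_condition,
                                measures = measures, path = path))
  criterion <- success_criterion(lapply(node$tests, parse_test, path = path))
  v <- validate_design(design, criterion)
  if (nrow(v) > 0L) {
    tg_stop("INVALID_DESIGN", paste0(
      path, ": ", where, " fails validation:\n",
      paste0("  [", v$code, "] ", v$message, collapse = "\n")))
  }
  list(label = design$study_label, design = design, criterion = criterion)
}

#' Read a multi-study analysis specification from YAML
#'
#' The file describes one or more studies — each a population model plus
#' its success criterion — and the threshold for the excess-success flag.
#' Parsing is strict: a `spec_version` field is required, unknown fields
#' are errors (catching typos rather than silently ignoring them), and
#' every design invariant is checked before the spec is returned.
#'
#' @param path Path to the YAML file.
#' @return A `paper_spec`: list with `label`, `studies` (each with
#'   `label`, `design`, `criterion`) and `tes_threshold`.
#' @seealso [write_spec()] for the inverse; `inst/extdata` of this package
#'   ships an example spec.
#' @export
read_spec <- function(path) {
  if (!file.exists(path)) {
    tg_stop("PARSE_ERROR", sprintf("%s: file not found", path))
  }
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) tg_stop(
                    "PARSE_ERROR", sprintf("%s: %s", path,
                                           conditionMessage(e))))
  check_fields(doc, c("spec_version", "label", "tes_threshold", "studies"),
               c("spec_version", "label", "studies"), "top level", path)
  if (!identical(as.integer(doc$spec_version), SPEC_VERSION)) {
    tg_stop("SCHEMA_VERSION_MISMATCH", sprintf(
      "%s: spec_version %s not supported (expected %d)", path,
      doc$spec_version, SPEC_VERSION))
  }
  studies <- lapply(doc$studies, parse_study, path = path)
  labels <- vapply(studies, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    tg_stop("PARSE_ERROR", sprintf("%s: duplicate study labels", path))
  }
  threshold <- doc$tes_threshold %||% 0.1
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    tg_stop("PARSE_ERROR",
            sprintf("%s: tes_threshold must lie in (0, 1)", path))
  }
  structure(list(label = as.character(doc$label), studies = studies,
                 tes_threshold = threshold),
            class = "paper_spec")
}

#' Assemble a multi-study specification in code
#'
#' Programmatic counterpart of [read_spec()]: bundles validated
#' design/criterion pairs under one label with an excess-success
#' threshold.
#'
#' @param label Identifier for the study set.
#' @param studies List whose elements are lists with `design` and
#'   `criterion` (study labels are taken from the designs).
#' @param tes_threshold Flagging cutoff in (0, 1).
#' @return A `paper_spec`.
#' @export
paper_spec <- function(label, studies, tes_threshold = 0.1) {
  studies <- lapply(studies, function(st) {
    v <- validate_design(st$design, st$criterion)
    if (nrow(v) > 0L) {
      tg_stop("INVALID_DESIGN", paste0(
        "study '", st$design$study_label, "' fails validation:\n",
        paste0("  [", v$code, "] ", v$message, collapse = "\n")))
    }
    list(label = st$design$study_label, design = st$design,
         criterion = st$criterion)
  })
  if (!is_scalar_number(tes_threshold) || tes_threshold <= 0 ||
      tes_threshold >= 1) {
    tg_stop("OUT_OF_RANGE", "tes_threshold must lie in (0, 1)")
  }
  structure(list(label = as.character(label), studies = studies,
                 tes_threshold = tes_threshold),
            class = "paper_spec")
}

test_spec_to_node <- function(ts) {
  node <- list(id = ts$test_id, kind = ts$kind, condition = ts$condition)
  if (!is.null(ts$condition_b)) node$condition_b <- ts$condition_b
  node$measure <- ts$measure
  if (!is.null(ts$measure_b)) node$measure_b <- ts$measure_b
  node$required <- ts$required
  if (!identical(ts$expected_sign, "none")) {
    node$expected_sign <- ts$expected_sign
  }
  node$alpha <- ts$alpha
  node
}

#' Write a `paper_spec` back to YAML
#'
#' Inverse of [read_spec()]: `read_spec(write_spec(x, path))` reproduces
#' `x` field for field.
#'
#' @param spec A `paper_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "paper_spec"))
  doc <- list(
    spec_version = SPEC_VERSION,
    label = spec$label,
    tes_threshold = spec$tes_threshold,
    studies = lapply(spec$studies, function(st) {
      measures <- st$design$conditions[[1L]]$model$measure_labels
      list(
        label = st$label,
        measures = as.list(measures),
        conditions = lapply(st$design$conditions, function(cond) {
          list(label = cond$label, sample_size = cond$n,
               means = as.list(cond$model$means),
               sds = as.list(cond$model$sds),
               correlations = lapply(
                 seq_len(nrow(cond$model$correlations)),
                 function(i) as.list(cond$model$correlations[i, ])))
        }),
        tests = lapply(st$criterion$tests, test_spec_to_node)
      )
    })
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

report_rows <- function(estimates, aggregate) {
  empty <- data.frame(
    record = character(), study = character(), test_id = character(),
    requirement = character(), marginal_rate = numeric(),
    p_hat = numeric(), mc_se = numeric(), reps = integer(),
    seed = integer(), p_tes = numeric(), threshold = numeric(),
    excess_flag = logical(), stringsAsFactors = FALSE)
  rows <- list(empty)
  for (est in estimates) {
    for (id in names(est$per_test_rates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = "marginal", study = est$study_label, test_id = id,
        requirement = est$requirements[[id]],
        marginal_rate = est$per_test_rates[[id]], p_hat = NA_real_,
        mc_se = NA_real_, reps = NA_integer_, seed = NA_integer_,
        p_tes = NA_real_, threshold = NA_real_, excess_flag = NA,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      record = "study", study = est$study_label, test_id = NA_character_,
      requirement = NA_character_, marginal_rate = NA_real_,
      p_hat = est$p_hat, mc_se = est$mc_se, reps = est$reps,
      seed = est$seed, p_tes = NA_real_, threshold = NA_real_,
      excess_flag = NA, stringsAsFactors = FALSE)
  }
  if (!is.null(aggregate)) {
    rows[[length(rows) + 1L]] <- data.frame(
      record = "aggregate", study = NA_character_, test_id = NA_character_,
      requirement = NA_character_, marginal_rate = NA_real_,
      p_hat = NA_real_, mc_se = NA_real_, reps = NA_integer_,
      seed = NA_integer_, p_tes = aggregate$p_tes,
      threshold = aggregate$threshold, excess_flag = aggregate$excess_flag,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Serialize estimation results to CSV or JSON
#'
#' CSV emits one tidy table: per-test marginal rows
#' (`study, test_id, requirement, marginal_rate`), per-study rows
#' (`study, p_hat, mc_se, reps, seed`) and, when an aggregate is given,
#' one aggregate row (`p_tes, threshold, excess_flag`). JSON mirrors the
#' full data model at full numeric precision; display rounding is left to
#' consumers.
#'
#' @param estimates List of `success_estimate` objects (may be empty).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param aggregate Optional `multi_study_result` from
#'   [aggregate_product()].
#' @return `path`, invisibly.
#' @export
write_report <- function(estimates, path, format = c("csv", "json"),
                         aggregate = NULL) {
  format <- match.arg(format)
  if (inherits(estimates, "success_estimate")) estimates <- list(estimates)
  if (format == "csv") {
    write.csv(report_rows(estimates, aggregate), path, row.names = FALSE)
  } else {
    payload <- list(
      estimates = lapply(estimates, function(est) {
        list(study = est$study_label, p_hat = est$p_hat, reps = est$reps,
             mc_se = est$mc_se,
             per_test_rates = as.list(est$per_test_rates),
             requirements = as.list(est$requirements),
             seed = est$seed, variant = est$variant,
             enforce_direction = est$enforce_direction)
      }),
      aggregate = if (!is.null(aggregate)) {
        list(per_study = as.list(aggregate$per_study),
             p_tes = aggregate$p_tes, threshold = aggregate$threshold,
             excess_flag = aggregate$excess_flag)
      }
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}
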