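example_spec_path <- function() {
  system.file("extdata", "example_spec.yaml", package = "toogood")
}

test_that("the shipped example spec parses and validates", {
  ps <- read_spec(example_spec_path())
  expect_s3_class(ps, "paper_spec")
  expect_identical(ps$label, "example_set")
  expect_length(ps$studies, 2L)
  expect_identical(ps$tes_threshold, 0.1)
  st <- ps$studies[[1L]]
  expect_identical(st$label, "priming_study")
  expect_length(st$criterion$tests, 3L)
  expect_identical(nrow(validate_design(st$design, st$criterion)), 0L)
})

test_that("specs round-trip through YAML field for field", {
  ps <- read_spec(example_spec_path())
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec(ps, path)
  back <- read_spec(path)
  expect_equal(back, ps, tolerance = 1e-12)

  # a programmatically built spec round-trips too
  fx <- make_random_design(fixture_config(seed = 77))
  ps2 <- paper_spec("fixture_set", list(fx), tes_threshold = 0.2)
  write_spec(ps2, path)
  back2 <- read_spec(path)
  expect_identical(back2$tes_threshold, 0.2)
  expect_equal(back2$studies[[1L]]$design, ps2$studies[[1L]]$design,
               tolerance = 1e-12)
  expect_equal(back2$studies[[1L]]$criterion, ps2$studies[[1L]]$criterion,
               tolerance = 1e-12)
})

test_that("strict parsing reports unknown fields, versions, violations", {
  path <- withr::local_tempfile(fileext = ".yaml")
  base <- readLines(example_spec_path())

  writeLines(c(base, "typo_field: 1"), path)
  expect_error(read_spec(path), "typo_field", class = "PARSE_ERROR")

  writeLines(sub("spec_version: 1", "spec_version: 99", base), path)
  expect_error(read_spec(path), class = "SCHEMA_VERSION_MISMATCH")

  writeLines(sub("^label: example_set", "xlabel: x", base), path)
  expect_error(read_spec(path), class = "PARSE_ERROR")

  # an invalid design inside an otherwise well-formed file
  writeLines(sub("sample_size: 13", "sample_size: 1", base), path)
  expect_error(read_spec(path), class = "INVALID_DESIGN")

  expect_error(read_spec(file.path(tempdir(), "missing.yaml")),
               class = "PARSE_ERROR")
})

test_that("reports serialize estimates, marginals and the aggregate", {
  d <- two_group_design(mu_a = 0.5, mu_b = 0)
  crit <- success_criterion(list(between_sig(sign = "positive"),
                                 between_nonsig(id = "t_extra")))
  est <- estimate_success(d, crit, reps = 1000, seed = 6)

  csv <- withr::local_tempfile(fileext = ".csv")
  agg <- aggregate_product(c(s1 = est$p_hat, s2 = 0.5))
  write_report(list(est), csv, format = "csv", aggregate = agg)
  tab <- read.csv(csv)
  expect_identical(sum(tab$record == "marginal"), 2L)
  expect_identical(sum(tab$record == "study"), 1L)
  expect_identical(sum(tab$record == "aggregate"), 1L)
  marg <- tab[tab$record == "marginal", ]
  expect_setequal(marg$test_id, c("t_sig", "t_extra"))
  expect_setequal(marg$requirement, c("significant", "nonsignificant"))
  arow <- tab[tab$record == "aggregate", ]
  expect_equal(arow$p_tes, agg$p_tes, tolerance = 1e-12)

  # empty input produces a header-only table
  write_report(list(), csv, format = "csv")
  empty <- read.csv(csv)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("study", "test_id", "requirement", "marginal_rate",
                    "p_hat", "mc_se", "reps", "seed") %in% names(empty)))
})

test_that("JSON reports reconstruct the estimate exactly", {
  d <- two_group_design(mu_a = 0.3, mu_b = 0)
  crit <- success_criterion(between_sig(sign = "positive"))
  est <- estimate_success(d, crit, reps = 1000, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(est), path, format = "json")
  back <- jsonlite::fromJSON(path)
  expect_identical(back$estimates$study, est$study_label)
  expect_identical(back$estimates$reps, est$reps)
  expect_identical(back$estimates$seed, est$seed)
  # doubles survive the decimal round trip to the serializer's precision
  expect_equal(back$estimates$p_hat, est$p_hat, tolerance = 1e-14)
  expect_equal(back$estimates$mc_se, est$mc_se, tolerance = 1e-14)
  expect_equal(back$estimates$per_test_rates$t_sig,
               unname(est$per_test_rates["t_sig"]), tolerance = 1e-14)
})

test_that("the five-study aggregate row reproduces the printed product", {
  agg <- aggregate_product(c(study1 = 0.163, study2 = 0.380,
                             study3 = 0.575, study4 = 0.450,
                             study5 = 0.212))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(list(), path, format = "csv", aggregate = agg)
  tab <- read.csv(path)
  expect_equal(round(tab$p_tes[tab$record == "aggregate"], 3), 0.003)
})
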