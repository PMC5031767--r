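test_that("random fixtures always pass validation and are simulable", {
  for (seed in 1:100) {
    cfg <- fixture_config(seed = seed,
                          n_conditions = 2L + seed %% 3L,
                          n_measures = 1L + seed %% 3L,
                          mix = (seed %% 5L) / 5L + 0.1)
    fx <- make_random_design(cfg)
    v <- validate_design(fx$design, fx$criterion)
    expect_identical(nrow(v), 0L, info = paste("seed", seed))
  }
  # end-to-end: a subsample estimates without error
  for (seed in c(3L, 17L, 55L)) {
    fx <- make_random_design(fixture_config(seed = seed))
    est <- estimate_success(fx$design, fx$criterion, reps = 200,
                            seed = seed)
    expect_true(est$p_hat >= 0 && est$p_hat <= 1)
  }
})

test_that("fixture generation is deterministic and respects the config", {
  cfg <- fixture_config(seed = 123)
  expect_identical(make_random_design(cfg), make_random_design(cfg))

  one_measure <- make_random_design(fixture_config(seed = 5,
                                                   n_measures = 1L))
  kinds <- vapply(one_measure$criterion$tests, `[[`, "", "kind")
  expect_false(any(kinds == "within"))

  expect_error(fixture_config(n_conditions = 1L, n_measures = 1L),
               class = "BAD_CONFIG")
  expect_error(fixture_config(n_range = c(1L, 5L)), class = "BAD_CONFIG")
  expect_error(fixture_config(corr_range = c(-0.5, 1)),
               class = "BAD_CONFIG")
})

test_that("the priming-study template has the documented structure", {
  tpl <- synthetic_study1()
  expect_identical(nrow(validate_design(tpl$design, tpl$criterion)), 0L)

  ns <- vapply(tpl$design$conditions, `[[`, 0L, "n")
  labels <- vapply(tpl$design$conditions, `[[`, "", "label")
  expect_identical(ns, c(13L, 12L, 14L))
  expect_identical(labels, c("white_prime", "no_prime", "black_prime"))

  tests <- tpl$criterion$tests
  kinds <- vapply(tests, `[[`, "", "kind")
  reqs <- vapply(tests, `[[`, "", "required")
  expect_identical(sum(kinds == "between" & reqs == "significant"), 3L)
  expect_identical(sum(kinds == "within" & reqs == "significant"), 2L)
  expect_identical(sum(kinds == "between" & reqs == "nonsignificant"), 2L)
  expect_identical(length(tests), 7L)
  # the non-significance requirements sit on the crime-irrelevant measure
  irr <- vapply(tests[reqs == "nonsignificant"], `[[`, "", "measure")
  expect_true(all(irr == "crime_irrelevant"))
})

test_that("five simultaneous null rejections are nearly impossible", {
  # all condition means equal: every significance requirement is a null
  # rejection, so joint success is bounded by an alpha^5-order term
  flat <- measure_model(c("crime_relevant", "crime_irrelevant"),
                        means = c(24, 24), sds = c(6, 6),
                        correlations = matrix(c(1, .4, .4, 1), 2))
  tpl <- study1_template(list(white_prime = flat, no_prime = flat,
                              black_prime = flat))
  est <- estimate_success(tpl$design, tpl$criterion, reps = 10000,
                          seed = 14)
  expect_lt(est$p_hat, 0.01)
})

test_that("the template requires explicit, complete parameters", {
  flat <- measure_model(c("crime_relevant", "crime_irrelevant"),
                        c(0, 0), c(1, 1))
  expect_error(study1_template(list(white_prime = flat)),
               class = "BAD_CONFIG")
  wrong_measures <- measure_model(c("a", "b"), c(0, 0), c(1, 1))
  expect_error(study1_template(list(white_prime = wrong_measures,
                                    no_prime = wrong_measures,
                                    black_prime = wrong_measures)),
               class = "BAD_CONFIG")
})

test_that("parameter files round-trip exactly", {
  tpl_params <- load_parameters(system.file(
    "extdata", "study1_synthetic_params.csv", package = "toogood"))
  expect_named(tpl_params, c("white_prime", "no_prime", "black_prime"))

  # write arbitrary models out and read them back
  models <- list(
    c1 = measure_model(c("x", "y", "z"), c(0.123456789012, 2, -1),
                       c(1.5, 2.25, 0.333333333333),
                       matrix(c(1, .2, .3, .2, 1, -.1, .3, -.1, 1), 3)),
    c2 = measure_model(c("x", "y", "z"), c(5, 6, 7), c(1, 1, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameters(models, path)
  back <- load_parameters(path)
  for (cl in names(models)) {
    expect_equal(back[[cl]]$means, models[[cl]]$means, tolerance = 1e-12)
    expect_equal(back[[cl]]$sds, models[[cl]]$sds, tolerance = 1e-12)
    expect_equal(back[[cl]]$correlations, models[[cl]]$correlations,
                 tolerance = 1e-12)
    expect_identical(back[[cl]]$measure_labels,
                     models[[cl]]$measure_labels)
  }
})

test_that("malformed parameter files raise PARSE_ERROR", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("condition,measure,mean", "a,x,1"), path)  # sd missing
  expect_error(load_parameters(path), class = "PARSE_ERROR")

  writeLines(c("condition,measure,mean,sd", "a,x,1,oops"), path)
  expect_error(load_parameters(path), class = "PARSE_ERROR")

  expect_error(load_parameters(file.path(tempdir(), "nope.csv")),
               class = "PARSE_ERROR")

  # inconsistent measure sets across conditions
  writeLines(c("condition,measure,mean,sd", "a,x,1,1", "b,y,1,1"), path)
  expect_error(load_parameters(path), class = "PARSE_ERROR")
})
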