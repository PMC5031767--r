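test_that("condition sampling reproduces the population model", {
  rho <- 0.9
  cond <- condition_spec("c", 100000L, measure_model(
    c("x", "y"), means = c(10, 20), sds = c(1, 2),
    correlations = matrix(c(1, rho, rho, 1), 2)))
  set.seed(11)
  tab <- sample_condition(cond)
  n <- nrow(tab)
  # column means within 4 standard errors of the population means
  expect_lt(abs(mean(tab$x) - 10), 4 / sqrt(n))
  expect_lt(abs(mean(tab$y) - 20), 4 * 2 / sqrt(n))
  expect_equal(sd(tab$x), 1, tolerance = 0.02)
  expect_equal(sd(tab$y), 2, tolerance = 0.02)
  # Fisher-z standard error bounds the sample correlation deviation
  z_err <- abs(atanh(cor(tab$x, tab$y)) - atanh(rho))
  expect_lt(z_err, 4 / sqrt(n - 3))
})

test_that("sampling is deterministic given the RNG state", {
  cond <- condition_spec("c", 50L, measure_model(c("x", "y"), c(0, 1),
                                                 c(1, 1)))
  set.seed(99)
  first <- sample_condition(cond)
  set.seed(99)
  second <- sample_condition(cond)
  expect_identical(first, second)
})

test_that("a singular (perfectly correlated) model still samples", {
  cond <- condition_spec("c", 2000L, measure_model(
    c("x", "y"), c(0, 0), c(1, 1), matrix(c(1, 1, 1, 1), 2)))
  set.seed(5)
  tab <- sample_condition(cond)
  expect_equal(cor(tab$x, tab$y), 1, tolerance = 1e-12)
})

test_that("one simulated replication evaluates the full battery", {
  tpl <- synthetic_study1()
  set.seed(21)
  one <- simulate_once(tpl$design, tpl$criterion)
  expect_identical(nrow(one$results), 7L)
  expect_identical(one$success, all(one$results$met))
  expect_true(all(one$results$p_value >= 0 & one$results$p_value <= 1))
  expect_true(all(one$results$df > 0))
})

test_that("estimates are bitwise reproducible from the seed", {
  tpl <- synthetic_study1()
  a <- estimate_success(tpl$design, tpl$criterion, reps = 2000, seed = 42)
  b <- estimate_success(tpl$design, tpl$criterion, reps = 2000, seed = 42)
  expect_identical(a, b)
  c <- estimate_success(tpl$design, tpl$criterion, reps = 2000, seed = 43)
  expect_false(identical(a$p_hat, c$p_hat))
})

test_that("too few replications are rejected", {
  d <- two_group_design()
  crit <- success_criterion(between_nonsig())
  expect_error(estimate_success(d, crit, reps = 50),
               class = "INSUFFICIENT_REPS")
})

test_that("the conjunction never beats its weakest member", {
  for (seed in 1:10) {
    fx <- make_random_design(fixture_config(seed = seed))
    est <- estimate_success(fx$design, fx$criterion, reps = 500,
                            seed = seed)
    expect_lte(est$p_hat, min(est$per_test_rates))
    expect_gte(est$p_hat, 0)
    expect_lte(est$mc_se, 0.5 / sqrt(est$reps))
  }
})

test_that("the vectorised estimate agrees with repeated single runs", {
  tpl <- synthetic_study1()
  reps <- 400L
  est <- estimate_success(tpl$design, tpl$criterion, reps = 10000,
                          seed = 31)
  set.seed(77)
  wins <- sum(vapply(seq_len(reps), function(i) {
    simulate_once(tpl$design, tpl$criterion)$success
  }, NA))
  p_loop <- wins / reps
  se <- sqrt(est$p_hat * (1 - est$p_hat) / reps)
  expect_lt(abs(p_loop - est$p_hat), 4 * se)
})

test_that("independent tests multiply: joint rate is the product of powers", {
  # two significance requirements on disjoint condition pairs
  design <- study_design("prod", list(
    condition_spec("a1", 20, measure_model("m", 0.6, 1)),
    condition_spec("a2", 20, measure_model("m", 0, 1)),
    condition_spec("b1", 25, measure_model("m", 0.8, 1)),
    condition_spec("b2", 25, measure_model("m", 0, 1))))
  crit <- success_criterion(list(
    test_spec("tA", "between", condition = "a1", condition_b = "a2",
              measure = "m", required = "significant",
              expected_sign = "positive"),
    test_spec("tB", "between", condition = "b1", condition_b = "b2",
              measure = "m", required = "significant",
              expected_sign = "positive")))
  est <- estimate_success(design, crit, reps = 40000, seed = 8)
  p1 <- power_two_sample(0.6, 20, 20)[["p_sig_in_direction"]]
  p2 <- power_two_sample(0.8, 25, 25)[["p_sig_in_direction"]]
  expect_lt(abs(est$p_hat - p1 * p2), 3 * est$mc_se)
})

test_that("welch and pooled variants differ under unequal variances", {
  design <- study_design("uv", list(
    condition_spec("a", 10, measure_model("m", 0.5, 3)),
    condition_spec("b", 40, measure_model("m", 0, 0.5))))
  crit <- success_criterion(between_sig(sign = "positive"))
  pooled <- estimate_success(design, crit, reps = 20000, seed = 4,
                             variant = "pooled")
  welch <- estimate_success(design, crit, reps = 20000, seed = 4,
                            variant = "welch")
  # with the small group highly variable, pooled df overstates precision
  expect_false(isTRUE(all.equal(pooled$p_hat, welch$p_hat,
                                tolerance = 1e-3)))
})
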