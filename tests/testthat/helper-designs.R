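# Shared builders for small designs used across the suite.

two_group_design <- function(mu_a = 0, mu_b = 0, n_a = 15L, n_b = 15L,
                             sd_a = 1, sd_b = 1, label = "two_group") {
  study_design(label, list(
    condition_spec("a", n_a, measure_model("m", mu_a, sd_a)),
    condition_spec("b", n_b, measure_model("m", mu_b, sd_b))))
}

between_sig <- function(id = "t_sig", sign = "positive", alpha = 0.05) {
  test_spec(id, "between", condition = "a", condition_b = "b",
            measure = "m", required = "significant", expected_sign = sign,
            alpha = alpha)
}

between_nonsig <- function(id = "t_nonsig", alpha = 0.05) {
  test_spec(id, "between", condition = "a", condition_b = "b",
            measure = "m", required = "nonsignificant", alpha = alpha)
}

# the shipped synthetic parameter set for the three-condition template
synthetic_study1 <- function() {
  params <- load_parameters(system.file("extdata",
                                        "study1_synthetic_params.csv",
                                        package = "toogood"))
  study1_template(params)
}

# random single-test design/criterion pairs for oracle-equivalence checks
random_single_test <- function(seed) {
  fx <- make_random_design(fixture_config(
    seed = seed, n_conditions = 2L + seed %% 2L, n_measures = 2L,
    effect_range = c(0.1, 1), corr_range = c(-0.5, 0.7),
    n_range = c(8L, 30L), mix = 0.6))
  pick <- 1L + seed %% length(fx$criterion$tests)
  list(design = fx$design,
       criterion = success_criterion(list(fx$criterion$tests[[pick]])))
}
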