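# Shared fixtures, built in code.

base_params <- function(...) suppressWarnings(model_parameters(...))

flat_life_table <- function(q, ages = 50:110) life_table(ages, rep(q, length(ages)))

# Parameters with every disease/surgery flow switched off and all living-state
# utilities at 1: survival is governed purely by the life table.
inert_parameters <- function(discount_rate = 0, pretest = 0) {
  p <- base_params()
  p$transitions <- list(malignant_transformation = 0, death_malignant_ipmn = 0,
                        death_recurrence = 0, perioperative_mortality = 0,
                        recurrence_probability = 0,
                        pet_recurrence_risk_reduction = 0)
  p$utilities <- list(healthy_ipmn = 1, resection_year = 1,
                      post_resection_longterm = 1, recurrence = 1, death = 0)
  p$economics$discount_rate <- discount_rate
  p$economics$pretest_probability <- pretest
  suppressWarnings(validate_parameters(p))
}

run_both <- function(p, life_table = default_life_table()) {
  list(pet = run_strategy(p, "pet", life_table),
       ctmri = run_strategy(p, "ctmri", life_table))
}
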