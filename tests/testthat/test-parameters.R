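test_that("defaults carry the base-case inputs and validation warns about the resection mix", {
  expect_warning(p <- model_parameters(), "resection fractions")
  expect_equal(p$pet$sensitivity, 0.968)
  expect_equal(p$pet$specificity, 0.911)
  expect_equal(p$ctmri$sensitivity, 0.809)
  expect_equal(p$economics$wtp, 100000)
  expect_equal(p$economics$discount_rate, 0.03)
  expect_equal(p$economics$starting_age, 64.3)
  expect_equal(p$transitions$recurrence_probability, 0.167)
})

test_that("range violations raise errors that name the offending field", {
  p <- base_params()
  p$ctmri$sensitivity <- 1.2
  expect_error(validate_parameters(p), "ctmri.sensitivity")
  p <- base_params()
  p$costs$recurrence_cost <- -5
  expect_error(validate_parameters(p), "recurrence_cost")
  p <- base_params()
  p$utilities$death <- 0.1
  expect_error(validate_parameters(p), "death")
  p <- base_params()
  p$economics$discount_rate <- 1
  expect_error(validate_parameters(p), "discount_rate")
})

test_that("boundary values pass and validation is idempotent", {
  p <- base_params()
  for (f in c("mri_exam", "pet_exam", "pancreatoduodenectomy",
              "distal_resection", "recurrence_cost", "readmission_cost"))
    p$costs[[f]] <- 0
  v1 <- suppressWarnings(validate_parameters(p))
  v2 <- suppressWarnings(validate_parameters(v1))
  expect_identical(v1, v2)
})

test_that("config loading honours percent suffixes, unknown keys and use_defaults", {
  cfg <- system.file("extdata", "base_case.yaml", package = "ipmncea")
  p <- suppressWarnings(load_parameters(cfg))
  expect_equal(unclass(p), unclass(base_params()))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("use_defaults: true", "pet:", "  specificity_percent: 85.0"), path)
  p2 <- suppressWarnings(load_parameters(path))
  expect_equal(p2$pet$specificity, 0.85)
  expect_equal(p2$pet$sensitivity, 0.968)

  writeLines(c("use_defaults: true", "pet:", "  specifcity: 0.85"), path)
  expect_error(load_parameters(path), "unknown key")

  writeLines(c("pet:", "  specificity: 0.85"), path)
  expect_error(load_parameters(path), "use_defaults")

  writeLines(c("use_defaults: true", "pet:", "  sensitivity: 1.2"), path)
  expect_error(load_parameters(path), "pet.sensitivity")

  expect_error(load_parameters(file.path(tempdir(), "nope.yaml")), "not found")
})

test_that("write/load round-trip reproduces the parameter set", {
  p <- generate_parameters(seed = 42, scale = 0.15)
  path <- withr::local_tempfile(fileext = ".yaml")
  suppressWarnings(write_parameters(p, path))
  q <- suppressWarnings(load_parameters(path))
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
})

test_that("weighted surgery cost renormalizes the published 78/21 mix", {
  cs <- base_params()$costs
  expect_equal(weighted_surgery_cost(cs),
               (0.78 * 28623 + 0.21 * 13900) / 0.99, tolerance = 1e-12)
  expect_equal(round(weighted_surgery_cost(cs), 2), 25499.94)
  expect_equal(surgery_event_cost(cs), weighted_surgery_cost(cs) + 1930)
})
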