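test_that("parameter paths address and replace nested fields", {
  p <- base_params()
  p2 <- set_parameter(p, "ctmri.specificity", 0.65)
  expect_equal(p2$ctmri$specificity, 0.65)
  expect_equal(p2$pet$specificity, p$pet$specificity)
  expect_error(set_parameter(p, "ctmri.spec", 0.5), "unknown parameter path")
  expect_error(set_parameter(p, "specificity", 0.5), "section.field")
  expect_error(set_parameter(p, "ctmri.specificity", 1.5), "ctmri.specificity")
})

test_that("one-way DSA brackets the base case and honours degenerate ranges", {
  p <- base_params()
  b <- p$ctmri$specificity
  ranges <- data.frame(parameter = c("ctmri.specificity", "costs.pet_exam"),
                       low = c(0.65, 1551), base = c(b, 1551),
                       high = c(0.85, 1551))
  tor <- one_way_dsa(p, ranges)
  expect_equal(nrow(tor), 2)
  # degenerate range: zero-width bar
  i <- which(tor$parameter == "costs.pet_exam")
  expect_equal(tor$dcost_low[i], tor$dcost_high[i])
  expect_equal(tor$deff_low[i], tor$deff_high[i])
  # base = base reproduces the base-case incremental exactly
  expect_equal(tor$dcost_low[i], attr(tor, "base_dcost"), tolerance = 1e-12)
  expect_equal(tor$deff_low[i], attr(tor, "base_deff"), tolerance = 1e-12)
  # worse CT/MRI specificity widens the PET advantage
  j <- which(tor$parameter == "ctmri.specificity")
  expect_gt(tor$deff_low[j], tor$deff_high[j])

  bad <- data.frame(parameter = "ctmri.specificity",
                    low = 0.9, base = 0.762, high = 0.95)
  expect_error(one_way_dsa(p, bad), "low <= base <= high")
  invalid <- data.frame(parameter = "ctmri.specificity",
                        low = 0.5, base = 0.762, high = 1.2)
  expect_error(one_way_dsa(p, invalid), "ctmri.specificity")
})

test_that("default ranges respect validity and published literature spans", {
  p <- base_params()
  r <- default_dsa_ranges(p)
  expect_true(all(r$low <= r$base & r$base <= r$high))
  expect_equal(r$low[r$parameter == "ctmri.specificity"], 0.65)
  expect_equal(r$high[r$parameter == "ctmri.specificity"], 0.85)
  tor <- one_way_dsa(p, r)
  expect_equal(sort(tor$parameter), sort(r$parameter))
})

test_that("bisection recovers a closed-form threshold to the requested tolerance", {
  # with all disease flows off, unit utilities, no discounting and equal
  # sensitivities, the NMB difference is linear in PET specificity:
  #   f(x) = -pet_exam - (1 - prev) * (sp_ctmri - x) * surgery_cost
  p <- inert_parameters(discount_rate = 0, pretest = 0.52)
  p$pet$sensitivity <- p$ctmri$sensitivity
  p <- suppressWarnings(validate_parameters(p))
  surgery <- surgery_event_cost(p$costs)
  root <- p$ctmri$specificity +
    p$costs$pet_exam / ((1 - 0.52) * surgery) # = 0.8798
  th <- threshold_analysis(p, "pet.specificity", interval = c(0.6, 0.99),
                           tol = 1e-4)
  expect_true(th$crossing)
  expect_equal(th$threshold, root, tolerance = 2e-4)

  # constant-sign interval: no crossing
  p0 <- p; p0$costs$pet_exam <- 0
  p0 <- suppressWarnings(validate_parameters(p0))
  th0 <- threshold_analysis(p0, "pet.specificity", interval = c(0.80, 0.99))
  expect_false(th0$crossing)
  expect_true(is.na(th0$threshold))

  expect_error(threshold_analysis(p, interval = c(0.9, 0.6)), "increasing")
  expect_error(threshold_analysis(p, tol = 0), "positive")
})

test_that("PET NMB is monotone in PET specificity and the sweep matches the analysis", {
  p <- base_params()
  sw <- threshold_sweep(p, values = seq(0.55, 0.95, by = 0.05))
  expect_true(all(diff(sw$nmb_pet) > 0))
  expect_true(all(abs(diff(sw$nmb_ctmri)) < 1e-6)) # CT/MRI arm unaffected
  th <- threshold_analysis(p)
  expect_true(th$crossing)
  f <- approxfun(sw$value, sw$nmb_pet - sw$nmb_ctmri)
  expect_lt(abs(f(th$threshold)), abs(f(th$threshold + 0.02)))
})
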