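test_that("net monetary benefit follows its defining identity exactly", {
  expect_equal(net_monetary_benefit(0, 0, 100000), 0)
  expect_equal(net_monetary_benefit(100000, 1, 100000), 0)
  expect_error(net_monetary_benefit(1, 1, -5), "non-negative")
  set.seed(8)
  for (i in 1:20) {
    cost <- stats::runif(1, 0, 2e5); eff <- stats::runif(1, 0, 15)
    wtp <- stats::runif(1, 0, 2e5)
    r <- strategy_result("x", cost, eff, wtp)
    expect_identical(r$nmb, wtp * eff - cost)
  }
})

test_that("published base-case table obeys the NMB identity within print rounding", {
  ref <- published_base_case()
  # effectiveness is printed to two decimals: agreement within half a unit
  # of the last printed digit
  expect_lt(abs((ref$pet_nmb + ref$pet_cost) / 1e5 - ref$pet_qaly), 0.005)
  expect_lt(abs((ref$ctmri_nmb + ref$ctmri_cost) / 1e5 - ref$ctmri_qaly), 0.005)
})

test_that("incremental analysis classifies dominance and computes ICERs", {
  a <- strategy_result("A", 100, 2, 1e5)
  self <- incremental_analysis(a, a)
  expect_equal(self$incremental_cost, 0)
  expect_equal(self$incremental_effectiveness, 0)
  expect_true(is.na(self$icer))

  b <- strategy_result("B", 50, 1, 1e5)
  ab <- incremental_analysis(a, b)
  expect_equal(ab$incremental_cost, -50)
  expect_equal(ab$incremental_effectiveness, -1)
  expect_equal(ab$icer, 50) # cheaper and less effective: a true tradeoff
  expect_equal(ab$dominance, "tradeoff")

  dom <- incremental_analysis(strategy_result("ref", 100, 1, 1e5),
                              strategy_result("new", 80, 2, 1e5))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))
  # antisymmetry under swapping the comparison
  expect_equal(incremental_analysis(strategy_result("new", 80, 2, 1e5),
                                    strategy_result("ref", 100, 1, 1e5))$dominance,
               "dominated")
  expect_error(incremental_analysis(a, strategy_result("B", 50, 1, 5e4)),
               "different WTP")
})

test_that("reference comparison reports deviations and applies tolerances", {
  vals <- c(cost = 100, qaly = 8)
  ref <- c(cost = 100, qaly = 8)
  cmp <- compare_to_reference(vals, ref,
                              list(cost = list(rel = 0.05),
                                   qaly = list(abs = 0.15)))
  expect_true(all(cmp$pass))
  expect_true(all(cmp$abs_dev == 0))

  cmp2 <- compare_to_reference(c(cost = 110), c(cost = 100),
                               list(cost = list(rel = 0.05)))
  expect_false(cmp2$pass)
  expect_equal(cmp2$rel_dev, 0.1)
  expect_error(compare_to_reference(c(x = 1), c(y = 1)), "no reference")
})
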