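test_that("cohort classification reproduces the hand-computed base-case splits", {
  pet <- classify_cohort(0.52, list(sensitivity = 0.968, specificity = 0.911))
  expect_equal(pet$tp, 0.52 * 0.968, tolerance = 1e-15)
  expect_equal(unlist(pet[c("tp", "fn", "tn", "fp")]),
               c(tp = 0.50336, fn = 0.01664, tn = 0.43728, fp = 0.04272),
               tolerance = 1e-12)
  ctmri <- classify_cohort(0.52, list(sensitivity = 0.809, specificity = 0.762))
  expect_equal(unlist(ctmri[c("tp", "fn", "tn", "fp")]),
               c(tp = 0.42068, fn = 0.09932, tn = 0.36576, fp = 0.11424),
               tolerance = 1e-12)
  none <- classify_cohort(0, list(sensitivity = 0.5, specificity = 1))
  expect_equal(none$tn, 1)
  expect_equal(none$tp + none$fp + none$fn, 0)
})

test_that("splits sum to one and accuracy moves mass only along its own margin", {
  set.seed(3)
  for (i in 1:25) {
    prev <- stats::runif(1)
    se <- stats::runif(1); sp <- stats::runif(1)
    s <- classify_cohort(prev, list(sensitivity = se, specificity = sp))
    expect_equal(s$tp + s$fp + s$tn + s$fn, 1, tolerance = 1e-12)
    expect_equal(s$tp + s$fn, prev, tolerance = 1e-12)
    s2 <- classify_cohort(prev, list(sensitivity = min(1, se + 0.1),
                                     specificity = sp))
    expect_gte(s2$tp, s$tp); expect_lte(s2$fn, s$fn)
    expect_equal(s2$tn, s$tn); expect_equal(s2$fp, s$fp)
  }
})

test_that("initial allocation applies surgery, perioperative mortality and imaging", {
  p <- base_params()
  split <- classify_cohort(0.52, p$pet)
  alloc <- initial_allocation(split, p, "pet")
  expect_equal(sum(alloc$state_occupancy), 1, tolerance = 1e-12)
  # perioperative deaths at cycle 0: (tp + fp) * 4.6%
  expect_equal(alloc$state_occupancy[["Death"]], 0.54608 * 0.046,
               tolerance = 1e-12)
  surgery <- surgery_event_cost(p$costs)
  expect_equal(alloc$upfront_cost, 492 + 1551 + 0.54608 * surgery,
               tolerance = 1e-9)
  expect_equal(alloc$upfront_utility,
               0.54608 * (1 - 0.046) * 0.818 + (1 - 0.54608) * 1,
               tolerance = 1e-12)

  ct <- initial_allocation(classify_cohort(0.52, p$ctmri), p, "ctmri")
  expect_equal(ct$pathways$cost[ct$pathways$pathway == "tn"], 492)

  all_tn <- initial_allocation(classify_cohort(0, list(sensitivity = 1,
                                                       specificity = 1)),
                               p, "ctmri")
  expect_equal(all_tn$state_occupancy[["SurveillanceBenign"]], 1)
  expect_equal(all_tn$upfront_cost, 492)
  expect_error(initial_allocation(split, p, "mrpet"))
})
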