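test_that("transition matrices are stochastic and encode the competing-risk rule", {
  p <- base_params()
  lt02 <- flat_life_table(0.02)
  m <- build_transition_matrix(70, p, "ctmri", lt02)
  expect_equal(rowSums(m), setNames(rep(1, 6), health_states()), tolerance = 1e-12)
  expect_equal(m["Death", ], setNames(c(0, 0, 0, 0, 0, 1), health_states()))
  # competing risks: P(Recurrence -> Death) = 1 - (1 - q)(1 - 0.283)
  expect_equal(m["Recurrence", "Death"], 1 - (1 - 0.02) * (1 - 0.283),
               tolerance = 1e-15)
  expect_equal(m["Recurrence", "Death"], 0.29734, tolerance = 1e-12)

  lt0 <- flat_life_table(0)
  mp <- build_transition_matrix(70, p, "pet", lt0)
  # PET recurrence hazard reduced by 10%
  expect_equal(mp["PostResectionMalignant", "Recurrence"], 0.167 * 0.9,
               tolerance = 1e-15)
  expect_equal(mp["SurveillanceBenign", "UndetectedMalignant"], 0.0223)

  # no-event limit: identity except the detection flow out of undetected
  # malignancy (annual re-testing with the strategy's own sensitivity)
  pz <- inert_parameters()
  mz <- build_transition_matrix(70, pz, "ctmri", lt0)
  expected <- diag(6)
  dimnames(expected) <- list(health_states(), health_states())
  expected["UndetectedMalignant", "UndetectedMalignant"] <- 1 - 0.809
  expected["UndetectedMalignant", "PostResectionMalignant"] <- 0.809
  expect_equal(mz, expected, ignore_attr = TRUE)
})

test_that("no-mortality, unit-utility, undiscounted cohort accrues exactly 15 QALYs", {
  p <- inert_parameters(discount_rate = 0, pretest = 0.52)
  lt0 <- flat_life_table(0)
  for (s in c("pet", "ctmri")) {
    tr <- run_strategy(p, s, lt0)$trace
    expect_equal(attr(tr, "total_qaly"), 15)
  }
})

test_that("two-state toy matches the geometric-series closed form exactly", {
  p <- inert_parameters(discount_rate = 0, pretest = 0)
  tr <- run_strategy(p, "ctmri", flat_life_table(0.1))$trace
  expect_equal(attr(tr, "total_qaly"), sum(0.9^(0:14)), tolerance = 1e-14)
  expect_equal(attr(tr, "total_qaly"), 7.94109, tolerance = 5e-6)
})

test_that("traces conserve mass, death is absorbing and totals accumulate", {
  for (seed in 0:19) {
    p <- generate_parameters(seed, 0.2)
    s <- if (seed %% 2 == 0) "pet" else "ctmri"
    tr <- run_strategy(p, s)$trace
    occ <- as.matrix(as.data.frame(tr)[, health_states()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
    expect_true(all(diff(occ[, "Death"]) >= -1e-15))
    expect_true(all(diff(tr$cum_dcost) >= 0))
    expect_true(all(diff(tr$cum_dqaly) >= 0))
  }
})

test_that("discounting bounds hold: QALYs <= discounted life-years <= annuity", {
  p <- base_params()
  for (s in c("pet", "ctmri")) {
    tr <- run_strategy(p, s)$trace
    df <- 1.03^-(0:14)
    ly <- sum((1 - as.data.frame(tr)$Death) * df)
    expect_lte(attr(tr, "total_qaly"), ly)
    expect_lte(ly, sum(df))
  }
  # discounted <= undiscounted for r > 0, equal at r = 0
  tr <- run_strategy(p, "pet")$trace
  expect_lte(sum(tr$dcost), sum(tr$cost))
  expect_lte(sum(tr$dqaly), sum(tr$qaly))
  p0 <- p; p0$economics$discount_rate <- 0
  tr0 <- run_strategy(suppressWarnings(validate_parameters(p0)), "pet")$trace
  expect_equal(sum(tr0$dcost), sum(tr0$cost))
})

test_that("equalizing PET accuracy, cost and recurrence benefit collapses the strategies", {
  p <- base_params()
  p$pet <- p$ctmri
  p$costs$pet_exam <- 0
  p$transitions$pet_recurrence_risk_reduction <- 0
  p <- suppressWarnings(validate_parameters(p))
  a <- run_strategy(p, "pet")$trace
  b <- run_strategy(p, "ctmri")$trace
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 0,
               ignore_attr = TRUE)
})

test_that("structural variants change the flows they claim to change", {
  p <- base_params()
  lt <- default_life_table()
  res <- function(p, s = "pet") run_strategy(suppressWarnings(validate_parameters(p)), s, lt)$result
  # one-time recurrence exposes less mass than five years, which exposes less
  # than the constant hazard
  p1 <- p; p1$structure$recurrence_model <- "one_time"
  p5 <- p; p5$structure$recurrence_model <- "first_five_years"
  expect_lt(res(p1)$cost, res(p5)$cost)
  expect_lt(res(p5)$cost, res(p)$cost)
  expect_gt(res(p1)$effectiveness, res(p)$effectiveness)
  # entry charging costs less than per-cycle, and both less than their sum
  pe <- p; pe$structure$recurrence_cost_timing <- "entry"
  pb <- p; pb$structure$recurrence_cost_timing <- "entry_and_cycle"
  expect_lt(res(pe)$cost, res(p)$cost)
  expect_equal(res(pb)$cost, res(pe)$cost + res(p)$cost -
                 res({px <- p; px$costs$recurrence_cost <- 0; px})$cost,
               tolerance = 1e-6)
  # half-cycle correction only touches utilities
  ph <- p; ph$structure$half_cycle_correction <- TRUE
  expect_equal(res(ph)$cost, res(p)$cost)
  expect_lt(res(ph)$effectiveness, res(p)$effectiveness)
  # dropping post-resection imaging can only save money
  pi0 <- p; pi0$structure$post_resection_imaging <- FALSE
  expect_lt(res(pi0)$cost, res(p)$cost)
  expect_equal(res(pi0)$effectiveness, res(p)$effectiveness)
})

test_that("trace export writes one row per cycle and re-reads identically", {
  tr <- run_strategy(base_params(), "pet")$trace
  path <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 15)
  expect_equal(back$cum_dcost[15], attr(tr, "total_cost"), tolerance = 1e-9)
})
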