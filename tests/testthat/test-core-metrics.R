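# Closed-form confusion-matrix algebra: examples with independently
# computed expectations, then property checks over random feasible
# scenarios.

test_that("sensitivity from relative risk matches the defining ratio equation", {
  # oracle: root-find on RR(s) = [s p / t] / [(1 - s) p / (1 - t)]
  oracle <- function(rr, t, p = 0.1) {
    stats::uniroot(
      function(s) (s * p / t) / ((1 - s) * p / (1 - t)) - rr,
      interval = c(1e-12, 1 - 1e-12), tol = 1e-14
    )$root
  }
  expect_equal(sensitivity_from_relative_risk(9, 0.10), 0.5)
  expect_equal(sensitivity_from_relative_risk(1, 0.25), 0.25)
  expect_equal(sensitivity_from_relative_risk(4.7, 0.05),
               oracle(4.7, 0.05), tolerance = 1e-9)
  expect_equal(sensitivity_from_relative_risk(4.7, 0.05), 0.19831, tolerance = 1e-4)
  for (case in list(c(2.5, 0.3), c(0.5, 0.6), c(12, 0.02))) {
    expect_equal(sensitivity_from_relative_risk(case[1], case[2]),
                 oracle(case[1], case[2]), tolerance = 1e-9)
  }
  expect_error(sensitivity_from_relative_risk(0, 0.1), class = "riskstrat_domain_error")
  expect_error(sensitivity_from_relative_risk(2, 1), class = "riskstrat_domain_error")
})

test_that("sensitivity from PPV inverts s*p/t = PPV and flags infeasible goals", {
  expect_equal(sensitivity_from_ppv(0.50, 0.08, 0.05), 0.3125)
  # chance-level classifier: PPV equal to prevalence gives s = t
  expect_equal(sensitivity_from_ppv(0.08, 0.08, 0.37), 0.37)
  # cross-parametrisation consistency: PPV 12% at p = 8%, t = 1/3 is RR = 2
  expect_equal(sensitivity_from_ppv(0.12, 0.08, 1 / 3),
               sensitivity_from_relative_risk(2, 1 / 3), tolerance = 1e-12)
  expect_error(sensitivity_from_ppv(0.9, 0.02, 0.5),
               class = "riskstrat_infeasible_error")
})

test_that("population 2x2 table has the right cells and margins", {
  cf <- confusion_from_scenario(cohort_scenario(0.02, 0.05, relative_risk = 4.7))
  s <- sensitivity_from_relative_risk(4.7, 0.05)
  expect_equal(cf$tp, s * 0.02)
  expect_equal(cf$fn, (1 - s) * 0.02)
  expect_equal(cf$tp + cf$fp + cf$fn + cf$tn, 1, tolerance = 1e-12)
  expect_equal(cf$tp + cf$fn, 0.02, tolerance = 1e-12)
  expect_equal(cf$tp + cf$fp, 0.05, tolerance = 1e-12)
  expect_equal(cf$tp, 0.003966, tolerance = 1e-4)

  # perfect classifier at t = p: empty off-diagonal
  cf2 <- confusion_from_scenario(cohort_scenario(0.02, 0.02, sensitivity = 1))
  expect_equal(unlist(cf2[c("tp", "fp", "fn", "tn")]),
               c(tp = 0.02, fp = 0, fn = 0, tn = 0.98))
})

test_that("classification summary reproduces worked metric values", {
  summ <- scenario_metrics(cohort_scenario(0.02, 0.05, relative_risk = 4.7))
  expect_equal(summ$ppv, 0.0793, tolerance = 1e-3)
  expect_equal(summ$npv, 0.9831, tolerance = 1e-4)
  expect_equal(summ$accuracy, 0.9379, tolerance = 1e-4)
  expect_equal(summ$specificity, 0.9530, tolerance = 1e-4)
  expect_equal(summ$relative_risk, 4.7, tolerance = 1e-9)

  summ2 <- scenario_metrics(cohort_scenario(0.05, 0.01, relative_risk = 6))
  expect_equal(summ2$ppv, 2 / 7, tolerance = 1e-9)

  # symmetric table: every metric 1/2, no risk concentration
  flat <- summarize_confusion(list(tp = 0.25, fp = 0.25, fn = 0.25, tn = 0.25))
  expect_equal(unlist(flat[c("ppv", "npv", "sensitivity", "specificity", "accuracy")]),
               c(ppv = .5, npv = .5, sensitivity = .5, specificity = .5, accuracy = .5))
  expect_equal(flat$relative_risk, 1)

  expect_error(summarize_confusion(list(tp = 0, fp = 0, fn = 0.02, tn = 0.98)),
               class = "riskstrat_degenerate_error")
})

test_that("integer percent rendering rounds halves away from zero", {
  expect_identical(round_percent(0.9379), 94L)
  expect_identical(round_percent(0.005), 1L)
  expect_identical(round_percent(0.065113), 7L)
  expect_identical(round_percent(c(0.225, 0.125)), c(23L, 13L))
  expect_error(round_percent(-0.1), class = "riskstrat_domain_error")
})

test_that("scenario construction rejects malformed or infeasible inputs", {
  expect_error(cohort_scenario(0, 0.1, sensitivity = 0.5), class = "riskstrat_domain_error")
  expect_error(cohort_scenario(0.1, 0.1), class = "riskstrat_domain_error")
  expect_error(cohort_scenario(0.1, 0.1, sensitivity = 0.5, ppv = 0.5),
               class = "riskstrat_domain_error")
  # PPV would exceed 1: half the cases cannot fit into 1% of the population
  expect_error(cohort_scenario(0.5, 0.01, relative_risk = 20),
               class = "riskstrat_infeasible_error")
})

test_that("case conservation and round-trips hold over random scenarios", {
  scenarios <- random_scenarios(400, seed = 11)
  for (sc in scenarios) {
    summ <- scenario_metrics(sc)
    p <- sc$prevalence
    t <- sc$target_fraction
    expect_lt(abs(summ$ppv * t + (1 - summ$npv) * (1 - t) - p), 1e-12)
    expect_lt(abs(summ$sensitivity * p - summ$ppv * t), 1e-12)
    # RR round-trip through the full pipeline
    expect_equal(summ$relative_risk, sc$discrimination_value, tolerance = 1e-9)
    # PPV round-trip
    sc2 <- cohort_scenario(p, t, ppv = summ$ppv)
    expect_equal(scenario_metrics(sc2)$ppv, summ$ppv, tolerance = 1e-12)
  }
})

test_that("metrics are nondecreasing in relative risk at fixed p and t", {
  for (pt in list(c(0.02, 0.05), c(0.2, 0.1), c(0.1, 0.5))) {
    rr_grid <- c(0.5, 1, 2, 4, 8, 16)
    if (pt[1] > pt[2])  # cap below the RR at which PPV reaches 1
      rr_grid <- rr_grid[rr_grid < (1 - pt[2]) / (pt[1] - pt[2])]
    vals <- sapply(rr_grid, function(rr) {
      s <- scenario_metrics(cohort_scenario(pt[1], pt[2], relative_risk = rr))
      c(s$ppv, s$sensitivity, s$specificity, s$npv)
    })
    for (r in 1:4) expect_true(all(diff(vals[r, ]) > -1e-12))
  }
})

test_that("sensitivity from relative risk does not depend on prevalence", {
  set.seed(42)
  for (i in 1:50) {
    rr <- exp(runif(1, log(0.3), log(15)))
    t <- runif(1, 0.02, 0.9)
    s0 <- sensitivity_from_relative_risk(rr, t)
    # the same (RR, t) embedded at random prevalences yields the same s
    for (p in runif(3, 0.005, 0.4)) {
      sc <- tryCatch(cohort_scenario(p, t, relative_risk = rr),
                     riskstrat_infeasible_error = function(e) NULL)
      if (!is.null(sc)) expect_equal(sc$sensitivity, s0, tolerance = 1e-12)
    }
  }
})
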