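test_that("event accounting follows the floor / half-up rounding chain", {
  p <- budget_params()
  expect_equal(expected_acu_events(p), 2177 * 0.1858)
  expect_equal(flagged_true_positives(p), 339L)
  expect_equal(prevented_events(p), 119L)
  # false positives: not-at-risk patients failing specificity
  expect_equal(false_positive_count(p), 2177 * (1 - 0.1858) * (1 - 0.51))
  expect_equal(round(false_positive_count(p), 1), 868.5)

  expect_equal(expected_acu_events(budget_params(p_prev = 0)), 0)
  expect_equal(expected_acu_events(budget_params(p_prev = 1)), 2177)
  expect_equal(flagged_true_positives(budget_params(r_sens = 0)), 0L)
  expect_equal(flagged_true_positives(
    budget_params(n_total = 100, p_prev = 0.5, r_sens = 1)), 50L)
  expect_equal(prevented_events(budget_params(p_pred = 0)), 0L)
  expect_equal(prevented_events(budget_params(p_pred = 1)),
               flagged_true_positives(p))
  expect_equal(false_positive_count(budget_params(r_spec = 1)), 0)
  expect_equal(false_positive_count(budget_params(p_prev = 1)), 0)

  expect_error(budget_params(p_prev = 1.2), "\\[0, 1\\]")
  expect_error(budget_params(c_acu = -1), ">= 0")
})

test_that("C0 and C1 follow the two cost equations", {
  p <- budget_params()
  expect_equal(cost_without_model(p, 0), 0)
  expect_equal(cost_without_model(p, 1), 17031.92 * 2177 * 0.1858)
  expect_equal(cost_without_model(p, 2), 2 * cost_without_model(p, 1))
  expect_error(cost_without_model(p, -1), ">= 0")

  # term-by-term at x = 1
  n0 <- expected_acu_events(p)
  expect_equal(cost_with_model(p, 1),
               1e6 + 112765 + 17031.92 * (n0 - 119))
  # with nothing prevented and no fixed costs, C1 = C0 + deployment
  free <- budget_params(p_pred = 0, c_annual = 0, c_nurse = 0, c_app = 0)
  expect_equal(cost_with_model(free, 1),
               free$c_deploy + cost_without_model(free, 1))
  # linear beyond year 1: constant first difference, zero second difference
  d1 <- cost_with_model(p, 2:6) - cost_with_model(p, 1:5)
  expect_equal(diff(d1), rep(0, 4))
  d0 <- cost_without_model(p, 2:6) - cost_without_model(p, 1:5)
  expect_equal(diff(d0), rep(0, 4))
  expect_error(cost_with_model(p, 0), ">= 1")
})

test_that("optional false-positive cost enters C1 but defaults to zero", {
  base <- budget_params()
  with_fp <- budget_params(c_fp = 100)
  expect_equal(cost_with_model(with_fp, 3) - cost_with_model(base, 3),
               100 * false_positive_count(base) * 3)
})

test_that("projection rows satisfy the savings and ROI identities", {
  p <- budget_params()
  proj <- projection(p, 6L)
  expect_equal(proj$year, 1:6)
  expect_equal(proj$cumulative_savings, cumsum(proj$savings))
  expect_equal(proj$cumulative_savings, proj$c0 - proj$c1)
  # year-1 savings identity
  expect_equal(proj$savings[1],
               119 * 17031.92 - 1e6 - 112765)
  expect_equal(headline_savings(proj$savings[1]), 910000)
  # horizon identity: cumulative = 6*C0(1) - C1(6), evaluated independently
  expect_equal(proj$cumulative_savings[6],
               6 * (17031.92 * 2177 * 0.1858) - cost_with_model(p, 6))
  expect_equal(proj$roi,
               proj$cumulative_savings /
                 (1e6 + 2e5 * (proj$year - 1) + 112765 * proj$year))

  # zero prevention: only costs remain, savings negative every year
  none <- projection(budget_params(p_pred = 0), 6L)
  expect_true(all(none$savings < 0))

  # with p_pred = 0 and all model costs zero, C1 == C0
  null <- budget_params(p_pred = 0, c_deploy = 0, c_annual = 0,
                        c_nurse = 0, c_app = 0)
  expect_equal(cost_with_model(null, 1:6), cost_without_model(null, 1:6))
  expect_error(projection(p, 0L), ">= 1")
})

test_that("savings are monotone in p_pred, r_sens, and c_acu", {
  at6 <- function(p) projection(p, 6L)$cumulative_savings[6]
  for (grid in list(
    lapply(seq(0, 1, 0.1), function(v) budget_params(p_pred = v)),
    lapply(seq(0, 1, 0.1), function(v) budget_params(r_sens = v)),
    lapply(seq(0, 4e4, 4e3), function(v) budget_params(c_acu = v))
  )) {
    vals <- vapply(grid, at6, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})
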