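test_that("group_summary reproduces published CCPD intervals to the cent", {
  a <- group_summary(mean = 94.62, sd = 72.54, n = 3820)
  expect_equal(round(a$ci_low, 2), 92.32)
  expect_equal(round(a$ci_high, 2), 96.92)
  b <- group_summary(mean = 53.28, sd = 59.92, n = 16736)
  expect_equal(round(b$ci_low, 2), 52.37)
  expect_equal(round(b$ci_high, 2), 54.19)

  cst <- group_summary(rep(5, 10))
  expect_equal(cst$sd, 0)
  expect_equal(cst$ci_low, 5)
  expect_equal(cst$ci_high, 5)

  v <- rnorm(50)
  s <- group_summary(v)
  expect_equal(s$mean - s$ci_low, s$ci_high - s$mean)  # symmetric
  expect_true(s$ci_low <= s$mean && s$mean <= s$ci_high)
  expect_error(group_summary(1), "n >= 2")
})

test_that("mann_whitney U matches the exhaustive pair-count oracle", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)  # complete separation

  same <- mann_whitney(1:20, 1:20)
  expect_gt(same$p_value, 0.9)

  set.seed(42)
  for (i in 1:25) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- sample(1:5, na, replace = TRUE)  # replacement forces ties
    b <- sample(1:5, nb, replace = TRUE)
    expect_equal(mann_whitney(a, b)$statistic, pair_count_U(a, b))
    # U_a + U_b = n_a * n_b including the tie halves
    expect_equal(pair_count_U(a, b) + pair_count_U(b, a), na * nb)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney normal-approximation p is close to permutation p", {
  set.seed(7)
  a <- rnorm(7); b <- rnorm(6, 0.5)
  approx_p <- mann_whitney(a, b)$p_value
  # exact permutation distribution of U over all reassignments
  pool <- c(a, b)
  combs <- utils::combn(13, 7)
  obs <- pair_count_U(a, b)
  us <- apply(combs, 2, function(ix) pair_count_U(pool[ix], pool[-ix]))
  mu <- 7 * 6 / 2
  perm_p <- mean(abs(us - mu) >= abs(obs - mu))
  expect_lt(abs(approx_p - perm_p), 0.05)
})

test_that("welch_t behaves on raw data and matches its summary-stats form", {
  same <- welch_t(1:10, 1:10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(3)
  b <- rnorm(50)
  a <- b + 10
  expect_lt(welch_t(a, b)$p_value, 0.001)

  # summary-stats route agrees with the raw route
  raw <- welch_t(a, b)
  ss <- welch_t_stats(mean(a), sd(a), 50, mean(b), sd(b), 50)
  expect_equal(ss$statistic, raw$statistic, tolerance = 1e-12)
  expect_equal(ss$df, raw$df, tolerance = 1e-12)
  expect_equal(ss$p_value, raw$p_value, tolerance = 1e-12)

  pooled_raw <- welch_t(a[1:20], b, var_equal = TRUE)
  pooled_ss <- welch_t_stats(mean(a[1:20]), sd(a[1:20]), 20,
                             mean(b), sd(b), 50, var_equal = TRUE)
  expect_equal(pooled_ss$p_value, pooled_raw$p_value, tolerance = 1e-12)

  # the published TCPP group table is significant at any level
  pub <- welch_t_stats(17031.92, 13056.63, 3820, 9591.06, 10785.83, 16736)
  expect_lt(pub$p_value, 0.001)

  expect_error(welch_t(1, 1:5), "n >= 2")
})

test_that("chi_square equals the direct sum((O-E)^2/E) formula", {
  tab <- matrix(c(10, 90, 30, 70), nrow = 2, byrow = TRUE)
  r <- chi_square(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - expected)^2 / expected))
  expect_equal(r$df, 1)

  ident <- matrix(c(20, 30, 40, 60), nrow = 2, byrow = TRUE)
  ri <- chi_square(ident)  # identical row distributions
  expect_equal(ri$statistic, 0)
  expect_equal(ri$p_value, 1)

  expect_error(chi_square(matrix(1:3, nrow = 1)), "at least 2 rows")
  expect_error(chi_square(matrix(c(1, 0, 2, 0), 2)), "expected")
})

test_that("interval_costs returns per-patient monotone cumulative checkpoints", {
  st <- small_study()
  study <- st$study
  cm <- build_cost_matrix(cost_services(study$services, study$table),
                          study$cohort, 180L)
  ic <- interval_costs(cm, c(30L, 90L, 180L))
  expect_equal(nrow(ic), 3L * length(cm$patient_id))

  wide <- reshape(ic, idvar = "patient_id", timevar = "day",
                  direction = "wide")
  expect_true(all(wide$cum_cost.30 <= wide$cum_cost.90))
  expect_true(all(wide$cum_cost.90 <= wide$cum_cost.180))
  # window end equals TCPP; day-1 checkpoint equals day-1 cost
  expect_equal(ic$cum_cost[ic$day == 180],
               unname(tcpp(cm))[match(ic$patient_id[ic$day == 180],
                                      cm$patient_id)])
  ic1 <- interval_costs(cm, 1L)
  expect_equal(ic1$cum_cost, unname(cm$daily[, 1]))

  expect_error(interval_costs(cm, 181L), "within")
})

test_that("compare_groups assembles summaries and tests for a cohort", {
  st <- small_study()
  study <- st$study
  cm <- build_cost_matrix(cost_services(study$services, study$table),
                          study$cohort, 180L)
  comp <- compare_groups(cm, study$cohort$acu_flag)
  expect_equal(nrow(comp$summaries), 4L)  # 2 groups x tcpp/ccpd
  expect_equal(nrow(comp$tests), 4L)      # MW + 3 checkpoints
  expect_true(all(comp$tests$p_value >= 0 & comp$tests$p_value <= 1))
  acu_mean <- comp$summaries$mean[comp$summaries$group == "acu" &
                                    comp$summaries$measure == "tcpp"]
  non_mean <- comp$summaries$mean[comp$summaries$group == "non_acu" &
                                    comp$summaries$measure == "tcpp"]
  expect_gt(acu_mean, non_mean)
})
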