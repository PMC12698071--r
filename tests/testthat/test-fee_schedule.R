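test_that("parsing validates layout, uniqueness, and referential integrity", {
  dir <- withr::local_tempdir()
  fees <- data.frame(code = c("P0001", "P0002", "J0001"),
                     year = 2020L, quarter = 1L,
                     work_rvu = c(1, 0.5, 0.2), pe_rvu = c(0.7, 0.4, 0.1),
                     mp_rvu = c(0.1, 0.05, 0.02),
                     asp_price = c(NA, NA, 120))
  write.csv(fees, file.path(dir, "fees.csv"), row.names = FALSE)
  write.csv(data.frame(year = 2020L, work_gpci = 1, pe_gpci = 1.1,
                       mp_gpci = 0.9),
            file.path(dir, "gpci.csv"), row.names = FALSE)
  write.csv(data.frame(year = 2020L, cf = 33),
            file.path(dir, "cf.csv"), row.names = FALSE)

  tab <- parse_fee_schedule(file.path(dir, "fees.csv"),
                            file.path(dir, "gpci.csv"),
                            file.path(dir, "cf.csv"))
  expect_s3_class(tab, "fee_schedule")
  expect_equal(nrow(tab$entries), 3L)

  expect_error(parse_fee_schedule(file.path(dir, "nope.csv"),
                                  file.path(dir, "gpci.csv"),
                                  file.path(dir, "cf.csv")),
               "not found")

  dup <- rbind(fees, fees[1, ])
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(parse_fee_schedule(file.path(dir, "dup.csv"),
                                  file.path(dir, "gpci.csv"),
                                  file.path(dir, "cf.csv")),
               "duplicate.*P0001\\|2020\\|1")

  fees2021 <- fees
  fees2021$year <- 2021L
  write.csv(fees2021, file.path(dir, "fees2021.csv"), row.names = FALSE)
  expect_error(parse_fee_schedule(file.path(dir, "fees2021.csv"),
                                  file.path(dir, "gpci.csv"),
                                  file.path(dir, "cf.csv")),
               "no GPCI")

  bad <- fees
  bad$work_rvu[1] <- -1
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(parse_fee_schedule(file.path(dir, "bad.csv"),
                                  file.path(dir, "gpci.csv"),
                                  file.path(dir, "cf.csv")),
               "RVU")

  extra <- cbind(fees, note = "x")
  write.csv(extra, file.path(dir, "extra.csv"), row.names = FALSE)
  expect_warning(parse_fee_schedule(file.path(dir, "extra.csv"),
                                    file.path(dir, "gpci.csv"),
                                    file.path(dir, "cf.csv")),
                 "unknown column")
})

test_that("quarter_of maps dates to calendar quarters by ceil(month/3)", {
  q <- quarter_of(as.Date(c("2020-01-01", "2020-12-31", "2015-07-15",
                            "2020-03-31", "2020-04-01")))
  expect_equal(q$year, c(2020L, 2020L, 2015L, 2020L, 2020L))
  expect_equal(q$quarter, c(1L, 4L, 3L, 1L, 2L))
  expect_error(quarter_of("not-a-date"), "invalid")
})

test_that("mpfs_fee is the three-component product-sum and linear in inputs", {
  gpci <- list(year = 2020L, work_gpci = 1.0, pe_gpci = 1.1, mp_gpci = 0.9)
  cf <- list(year = 2020L, cf = 33.0)

  zero <- list(year = 2020L, work_rvu = 0, pe_rvu = 0, mp_rvu = 0)
  expect_equal(mpfs_fee(zero, gpci, cf), 0)

  unit <- list(year = 2020L, work_rvu = 1, pe_rvu = 0, mp_rvu = 0)
  gpci1 <- list(year = 2020L, work_gpci = 1, pe_gpci = 1, mp_gpci = 1)
  expect_equal(mpfs_fee(unit, gpci1, list(year = 2020L, cf = 34.6062)),
               34.6062)

  entry <- list(year = 2020L, work_rvu = 1.3, pe_rvu = 0.7, mp_rvu = 0.1)
  # hand-computed product-sum: (1.3*1.0 + 0.7*1.1 + 0.1*0.9) * 33
  expect_equal(mpfs_fee(entry, gpci, cf), (1.3 + 0.77 + 0.09) * 33)

  # linearity in cf and in each RVU component
  for (k in c(2, 5)) {
    cfk <- list(year = 2020L, cf = 33 * k)
    expect_equal(mpfs_fee(entry, gpci, cfk), k * mpfs_fee(entry, gpci, cf))
    ek <- entry
    ek$work_rvu <- entry$work_rvu * k
    expect_equal(mpfs_fee(ek, gpci, cf) - mpfs_fee(entry, gpci, cf),
                 (k - 1) * entry$work_rvu * gpci$work_gpci * cf$cf)
  }

  expect_error(mpfs_fee(list(year = 2021L, work_rvu = 1, pe_rvu = 0,
                             mp_rvu = 0), gpci, cf),
               "does not match")
})

test_that("asp_fee applies the 106% CMS payment limit", {
  expect_equal(asp_fee(100), 106)
  expect_equal(asp_fee(0), 0)
  expect_equal(asp_fee(37.50), 39.75)
  expect_error(asp_fee(-1), ">= 0")
})

test_that("combined_fee sums MPFS and ASP and is quarter-indexed", {
  tab <- tiny_schedule()
  # non-drug code: MPFS only
  mpfs_p1 <- (1.3 * 1.0 + 0.7 * 1.1 + 0.1 * 0.9) * 33
  expect_equal(combined_fee(tab, "P0001", as.Date("2020-02-01")), mpfs_p1)
  # drug code: MPFS + 1.06 * ASP (Q1 price 100)
  mpfs_j <- (0.2 * 1.0 + 0.1 * 1.1 + 0.02 * 0.9) * 33
  expect_equal(combined_fee(tab, "J0001", as.Date("2020-02-01")),
               mpfs_j + 106)
  # ASP drifts by quarter -> different fee in Q3 (price 120)
  expect_equal(combined_fee(tab, "J0001", as.Date("2020-08-01")),
               mpfs_j + 1.06 * 120)
  # piecewise-constant within a quarter
  expect_equal(combined_fee(tab, "J0001", as.Date("2020-07-01")),
               combined_fee(tab, "J0001", as.Date("2020-09-30")))
  # error taxonomy
  expect_error(combined_fee(tab, "X9999", as.Date("2020-02-01")),
               "never seen")
  expect_error(combined_fee(tab, "P0001", as.Date("2021-02-01")),
               "no fee entry for 2021")
})

test_that("combined fees are non-negative across random schedules", {
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- synthetic_config(seed = seed, n_patients = 10L, n_codes = 30L)
    tab <- gen_fee_schedule(cfg)
    expect_true(all(acucost:::entry_fees(tab) >= 0))
  }
})

test_that("CSV round trip reproduces every fee bit-identically", {
  cfg <- synthetic_config(seed = 7L, n_patients = 10L, n_codes = 25L)
  set.seed(7L)
  tab <- gen_fee_schedule(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fee_schedule(tab, dir)
  tab2 <- parse_fee_schedule(paths[1], paths[2], paths[3])
  expect_identical(acucost:::entry_fees(tab), acucost:::entry_fees(tab2))
  expect_identical(tab$key, tab2$key)
})
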