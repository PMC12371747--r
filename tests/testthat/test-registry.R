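test_that("the inclusion cascade reproduces the registry exclusion flow", {
  # 840 eligible records; disjoint flags 61 / 34 / 71 leave 674
  coh <- make_cohort(840)
  coh$flag_adaptation[1:61] <- TRUE
  coh$flag_brachy[62:95] <- TRUE
  coh$flag_reirradiation[96:166] <- TRUE
  res <- apply_inclusion(coh)
  expect_equal(nrow(res$included), 674)
  counts <- setNames(res$tally$n_excluded, res$tally$criterion)
  expect_equal(unname(counts[c("plan_adaptation", "brachy_boost",
                               "reirradiation")]), c(61, 34, 71))
  expect_equal(attr(res$tally, "n_input"), 840)
  expect_equal(attr(res$tally, "n_remaining"), 674)
})

test_that("overlapping exclusion flags are attributed to the first criterion", {
  coh <- make_cohort(10)
  coh$flag_adaptation[1:3] <- TRUE
  coh$flag_brachy[3:5] <- TRUE       # record 3 overlaps with adaptation
  res <- apply_inclusion(coh)
  counts <- setNames(res$tally$n_excluded, res$tally$criterion)
  expect_equal(unname(counts["plan_adaptation"]), 3)
  expect_equal(unname(counts["brachy_boost"]), 2)
  expect_equal(nrow(res$included), 5)
})

test_that("inclusion handles edge cases and conserves counts", {
  empty <- make_cohort(0)
  res0 <- apply_inclusion(empty)
  expect_equal(nrow(res0$included), 0)
  expect_true(all(res0$tally$n_excluded == 0))

  # sub-curative prescription is excluded under the >= 50 Gy criterion
  coh <- make_cohort(3, dose = c(48, 50, 68))
  res <- apply_inclusion(coh)
  expect_equal(nrow(res$included), 2)
  counts <- setNames(res$tally$n_excluded, res$tally$criterion)
  expect_equal(unname(counts["dose_below_curative"]), 1)

  # conservation and idempotence on a messy cohort
  set.seed(21)
  messy <- make_cohort(60,
                       year = sample(2008:2024, 60, replace = TRUE),
                       dose = sample(c(45, 55, 68), 60, replace = TRUE),
                       fu_times = lapply(1:60, function(i)
                         round(runif(sample(0:2, 1), 1, 30), 1)))
  messy$followup_grades <- lapply(messy$followup_times, function(tt)
    rep(0L, length(tt)))
  messy$flag_brachy[sample(60, 8)] <- TRUE
  res <- apply_inclusion(messy)
  expect_equal(attr(res$tally, "n_input"),
               attr(res$tally, "n_remaining") + sum(res$tally$n_excluded))
  again <- apply_inclusion(res$included)
  expect_equal(nrow(again$included), nrow(res$included))
  expect_true(all(again$tally$n_excluded == 0))
})

test_that("unknown tumor sites raise a data error naming the record", {
  coh <- make_cohort(2)
  coh$tumor_site[2] <- "mystery"
  expect_error(apply_inclusion(coh), "mystery.*T0002")
})

test_that("follow-up selection picks the in-window time nearest 6 months", {
  expect_equal(select_followup(c(5, 8)), 1L)        # |5-6| < |8-6|
  expect_equal(select_followup(7), 1L)
  expect_true(is.na(select_followup(c(4, 30))))     # both outside [5, 24]
  expect_equal(select_followup(c(5, 7)), 1L)        # tie -> earlier visit
  expect_equal(select_followup(c(7, 5)), 2L)        # order-independent

  # property: the selected time is always inside the window
  set.seed(22)
  for (rep in 1:50) {
    tt <- runif(sample(1:5, 1), 0, 36)
    idx <- select_followup(tt, window = c(5, 24))
    if (!is.na(idx)) {
      expect_true(tt[idx] >= 5 && tt[idx] <= 24)
      inside <- tt[tt >= 5 & tt <= 24]
      expect_equal(min(abs(inside - 6)), abs(tt[idx] - 6))
    } else {
      expect_true(all(tt < 5 | tt > 24))
    }
  }
})

test_that("the binary endpoint is grade >= 2 xerostomia", {
  expect_equal(derive_endpoint(c(0, 1, 2, 3, 4)), c(0L, 0L, 1L, 1L, 1L))
  expect_error(derive_endpoint(5), "0-4")
})

test_that("cohort summaries report prevalence and dose quantiles", {
  coh <- make_cohort(10, fu_grades = list(2L, 2L, 2L, 0L, 0L,
                                          0L, 0L, 0L, 0L, 1L))
  s <- cohort_summary(coh)
  expect_equal(s$n_events, 3)
  expect_equal(s$prevalence_percent, 30)

  single <- make_cohort(1, parotid_ipsi = 33.3)
  s1 <- cohort_summary(single)
  expect_equal(unname(s1$gland_doses$parotid_ipsi_mean["median"]), 33.3)
  expect_equal(unname(s1$gland_doses$parotid_ipsi_mean["q25"]),
               unname(s1$gland_doses$parotid_ipsi_mean["q75"]))
  expect_error(cohort_summary(make_cohort(0)), "empty")
})

test_that("cohort comparison applies chi-square and t-tests per variable", {
  # identical groups: statistic 0, p = 1
  same <- list(categorical = list(site = c(a = 30, b = 20)),
               continuous = list(age = list(mean = 60, sd = 10, n = 50)))
  out <- cohort_compare(same, same)
  expect_equal(out$statistic[out$variable == "site"], 0)
  expect_equal(out$p_value[out$variable == "site"], 1)
  expect_equal(out$p_value[out$variable == "age"], 1)

  # published sex distribution: not significant
  sex <- cohort_compare(
    list(categorical = list(sex = c(male = 481, female = 193))),
    list(categorical = list(sex = c(male = 850, female = 295))))
  expect_gt(sex$p_value, 0.05)
  expect_false(sex$significant)

  # perfectly separated 2x2 table vs brute-force Pearson arithmetic
  sep <- cohort_compare(
    list(categorical = list(v = c(x = 10, y = 0))),
    list(categorical = list(v = c(x = 0, y = 10))))
  expect_equal(sep$statistic, 20)  # 4 cells, each (5)^2/5
  expect_lt(sep$p_value, 0.001)

  # summary-based t-test agrees with t.test on raw data
  set.seed(23)
  xa <- rnorm(80, 60, 9)
  xb <- rnorm(120, 63, 11)
  raw <- cohort_compare(list(continuous = list(age = xa)),
                        list(continuous = list(age = xb)))
  summ <- cohort_compare(
    list(continuous = list(age = list(mean = mean(xa), sd = sd(xa),
                                      n = length(xa)))),
    list(continuous = list(age = list(mean = mean(xb), sd = sd(xb),
                                      n = length(xb)))))
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
})

test_that("cohort CSVs round-trip including follow-up lists", {
  coh <- make_cohort(4,
                     fu_times = list(c(5.5, 12), 7, c(6, 18, 23), 9),
                     fu_grades = list(c(2L, 1L), 0L, c(3L, 2L, 2L), 1L))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$followup_times, coh$followup_times)
  expect_equal(back$followup_grades, coh$followup_grades)
  expect_equal(back$prescribed_dose_gy, coh$prescribed_dose_gy)
  unlink(f)
})
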