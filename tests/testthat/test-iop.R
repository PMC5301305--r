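test_that("tonometer aggregation is a plain mean with deviation warnings", {
  expect_equal(aggregate_readings(rep(15, 10)), 15)
  expect_equal(aggregate_readings(c(14, 15, 16, 15, 15, 14, 16, 15, 15, 15)), 15)
  expect_warning(v <- aggregate_readings(c(14, 16)), "deviation")
  expect_equal(v, 15)
  expect_error(aggregate_readings(numeric(0)), "No tonometer readings")
})

test_that("baseline IOP averages the pre-surgical block", {
  s <- tibble::tibble(timepoint = paste0("baseline_d", -5:-1),
                      value = c(14, 15, 16, 15, 15))
  expect_equal(baseline_iop(s), 15)
  expect_warning(b <- baseline_iop(s[1, ]), "deviation")
  expect_equal(b, 14)
  expect_error(baseline_iop(s[0, ]), "baseline")
})

test_that("course summary reproduces plateau delta and percent increase", {
  treated <- iop_series(baseline = 13.8, delta = 5.7)
  control <- iop_series(baseline = 13.8, delta = 0, eye = "control")
  s <- summarize_course(treated, control)
  expect_equal(attr(s, "delta"), 5.7, tolerance = 1e-9)
  expect_equal(attr(s, "percent_increase_rounded"), 41)
  # identical series give zero elevation
  s0 <- summarize_course(control, control)
  expect_equal(attr(s0, "delta"), 0)
  expect_equal(attr(s0, "percent_increase"), 0)
  # 19.7 vs 14.0 rounds to 41 as well
  t2 <- iop_series(baseline = 14, delta = 5.7)
  c2 <- iop_series(baseline = 14, delta = 0, eye = "control")
  expect_equal(round(attr(summarize_course(t2, c2), "percent_increase"), 1), 40.7)
  expect_equal(attr(summarize_course(t2, c2), "percent_increase_rounded"), 41)
})

test_that("simulated course follows the spike-decay-plateau schedule", {
  s <- iop_series(baseline = 14, delta = 5.7, spike = 38, tau = 2)
  # closed-form decay: day 3 = plateau + (spike - plateau) exp(-3/2)
  expect_equal(s$value[s$timepoint == "day3"],
               19.7 + (38 - 19.7) * exp(-3 / 2), tolerance = 1e-9)
  expect_equal(round(s$value[s$timepoint == "day3"], 1), 23.8)
  expect_true(all(s$value[grepl("^week", s$timepoint)] == 19.7))
  ctrl <- iop_series(baseline = 14, eye = "control")
  expect_true(all(ctrl$value == 14))
  # sham treated eyes revert to baseline from day 2 onward
  sham <- iop_series(baseline = 14, spike = 38, group = "sham")
  post <- sham$value[sham$timepoint %in% c("day2", "day3", paste0("week", 1:12))]
  expect_true(all(post == 14))
  expect_gt(sham$value[sham$timepoint == "2min"], 30)
  expect_error(simulate_iop_course(quiet_truth(), group = "bad"), "Unknown group")
})

test_that("group table returns mean and SEM with small-n flags", {
  cohort <- tibble::tibble(
    animal = c("a1", "a2"), eye = "treated", group = "OHT",
    timepoint = "week2", value = c(14, 16))
  g <- group_iop_table(cohort)
  expect_equal(g$mean, 15)
  expect_equal(g$sem, 1)  # sd = sqrt(2), sem = 1
  same <- cohort |> dplyr::mutate(value = 15)
  expect_equal(group_iop_table(same)$sem, 0)
  expect_warning(g1 <- group_iop_table(cohort[1, ]), "n < 2")
  expect_true(g1$flagged)
})

test_that("plateau mean is invariant to permuting weekly timepoints", {
  s <- iop_series(baseline = 14, delta = 5.7)
  shuffled <- withr::with_seed(1, s[sample(nrow(s)), ])
  ctrl <- iop_series(baseline = 14, eye = "control")
  expect_equal(attr(summarize_course(shuffled, ctrl), "delta"),
               attr(summarize_course(s, ctrl), "delta"))
})
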