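test_that("standard curve fit recovers the exact line", {
  cv <- fit_standard_curve(exact_curve_points())
  expect_equal(cv$slope, -3.32, tolerance = 1e-9)
  expect_equal(cv$intercept, 36.64, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$efficiency, 10^(1 / 3.32) - 1, tolerance = 1e-9)
  expect_error(fit_standard_curve(tibble::tibble(copies = c(100, 100),
                                                 ct = c(30, 29))), "distinct")
  expect_warning(fit_standard_curve(tibble::tibble(copies = c(100, 1000),
                                                   ct = c(20, 30))),
                 "non-negative")
})

test_that("a -3.322 slope means 100% efficiency", {
  pts <- tibble::tibble(copies = 10^(2:5), ct = 36.64 - 3.322 * (2:5))
  cv <- fit_standard_curve(pts)
  expect_equal(cv$efficiency, 1, tolerance = 1e-3)
})

test_that("quantification inverts the standard line", {
  cv <- fit_standard_curve(exact_curve_points())
  expect_equal(quantify(cv$intercept, cv), 1, tolerance = 1e-9)
  expect_equal(quantify(25, cv), 10^((36.64 - 25) / 3.32), tolerance = 1e-9)
  expect_equal(round(quantify(25, cv)), 3206)
  # a Ct one slope-magnitude lower means 10x the copies
  expect_equal(quantify(25 - 3.32, cv), 10 * quantify(25, cv), tolerance = 1e-9)
  expect_error(quantify(NaN, cv), "finite")
})

test_that("simulate-then-quantify is exact at zero noise", {
  tr <- quiet_truth()
  run <- simulate_qpcr_run(tr)
  for (g in unique(run$gene)) {
    cv <- fit_standard_curve(run |> dplyr::filter(gene == g, role == "standard") |>
                               dplyr::transmute(copies = nominal_copies, ct))
    smp <- run |> dplyr::filter(gene == g, role == "sample")
    expect_equal(sd(smp$ct), 0)  # noiseless triplicates identical
    nominal <- if (g == "Hprt") tr$expr$hprt_copies else
      tr$expr$ratios[[g]] * tr$expr$hprt_copies
    expect_equal(mean(quantify(smp$ct, cv)), nominal, tolerance = 1e-9)
  }
})

test_that("normalization and receptor ratio behave as plain ratios", {
  expect_equal(normalize_expression(960, 3200), 0.30)
  for (h in c(1, 100, 1e5)) {
    expect_equal(normalize_expression(0.31 * h, h), 0.31)
  }
  expect_error(normalize_expression(10, 0), "positive")
  expect_equal(receptor_ratio(0.5, 0.5), 1)
  expect_equal(receptor_ratio(0.6, 0.3), 2)
  expect_error(receptor_ratio(0.5, 0), "positive")
})

test_that("cohort qPCR analysis recovers configured expression at zero noise", {
  tr <- quiet_truth()
  study <- simulate_study(tiny_config(), tr, seed = 5)
  res <- analyze_qpcr(study$qpcr)
  ent <- res$expression |> dplyr::filter(gene == "Entpd1", group == "sham")
  expect_equal(ent$normalized, rep(0.28, nrow(ent)), tolerance = 1e-9)
  oht <- res$expression |>
    dplyr::filter(gene == "Entpd1", group == "OHT", eye == "treated")
  expect_equal(oht$normalized, rep(0.28 * 1.107, nrow(oht)), tolerance = 1e-9)
  expect_true(all(res$curves$flagged == FALSE))
  expect_equal(res$ratios$p2x7_adora3,
               rep(0.05 / 0.02, nrow(res$ratios)), tolerance = 1e-9)
  expect_error(analyze_qpcr(study$qpcr |> dplyr::mutate(gene = "Gapdh")),
               "panel")
})
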