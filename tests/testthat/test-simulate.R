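test_that("single-component pSTR truth peaks at the configured amplitude", {
  tr <- quiet_truth(erg = list(rm_p3 = 0, S = 1, vmax = 0, op_amplitude = 0,
                               pstr_amplitude = 12))
  fam <- simulate_erg_family(tr, tiny_config())
  # at the reference analysis energy the bump height is the truth value
  w <- fam |> dplyr::filter(energy_log == -5.01)
  expect_equal(max(w$voltage_uV), 12, tolerance = 1e-9)
  expect_equal(w$time_ms[which.max(w$voltage_uV)], 110, tolerance = 0.25)
})

test_that("simulated P3 matches the closed-form model", {
  tr <- quiet_truth(erg = list(rm_p3 = -500, S = 1000, td_ms = 3, vmax = 0,
                               op_amplitude = 0, pstr_amplitude = 1e-9))
  cfg <- cohort_config(n_oht = 2, n_sham = 2,
                       energy_grid = c(-6.35, -5.31, -5.01, -4.90, 0, 2.07))
  fam <- simulate_erg_family(tr, cfg)
  v <- fam$voltage_uV[fam$energy_log == 0 & fam$time_ms == 13]
  expect_equal(v, -500 * (1 - exp(-1000 * 1 * 0.010^2)), tolerance = 1e-9)
  expect_equal(round(v, 1), -47.6)
})

test_that("identical seeds reproduce waveforms and cohorts exactly", {
  tr <- study_truth()
  cfg <- tiny_config()
  expect_identical(simulate_erg_family(tr, cfg, seed = 3),
                   simulate_erg_family(tr, cfg, seed = 3))
  s1 <- simulate_study(cfg, tr, seed = 7)
  s2 <- simulate_study(cfg, tr, seed = 7)
  for (nm in c("waveforms", "iop", "oct", "doppler", "rgc", "qpcr",
               "ground_truth")) {
    expect_identical(s1[[nm]], s2[[nm]])
  }
  expect_error(simulate_erg_family(tr, cfg), "seed")
})

test_that("morphometry round-trips the configured structure", {
  tr <- quiet_truth(morph = list(rnfl = 12.3, trt = 230, bmo = 700, mrt = 150.4))
  m <- simulate_morphometry(tr, seed = 2)
  expect_equal(layer_thickness(m$boundaries, "rnfl"), 12.3, tolerance = 1e-9)
  expect_equal(layer_thickness(m$boundaries, "trt"), 230, tolerance = 1e-9)
  expect_equal(bmo_width(m$bmo_endpoints), 700, tolerance = 1e-9)
  expect_equal(minimum_rim_thickness(m$boundaries, m$bmo_endpoints), 150.4,
               tolerance = 1e-9)
  # Poisson count expectation: density x field area
  expect_equal(3531 * 0.29062^2, 298.2, tolerance = 1e-3)
  m2 <- simulate_morphometry(tr, seed = 2)
  expect_identical(m$rgc$count, m2$rgc$count)
  expect_error(simulate_morphometry(quiet_truth(morph = list(rnfl = -1))),
               "non-negative")
})

test_that("qPCR simulation honors the log-linear curve", {
  tr <- quiet_truth(expr = list(slope = -3.322, intercept = 36.64))
  run <- simulate_qpcr_run(tr, copies = c(Entpd1 = 1e4, Hprt = 1e4))
  ct <- run$ct[run$gene == "Entpd1" & run$role == "sample"]
  expect_equal(ct, rep(36.64 - 3.322 * 4, 3), tolerance = 1e-9)
  expect_equal(round(ct[1], 2), 23.35)
  expect_error(simulate_qpcr_run(quiet_truth(expr = list(standard_copies = 100))),
               "at least 2")
})

test_that("estimator spread grows with configured noise", {
  # qPCR: SD of recovered copies over replicates, three noise levels
  spread_at <- function(ct_sd) {
    reps <- vapply(1:100, function(r) {
      tr <- quiet_truth(noise = list(ct_sd = ct_sd))
      run <- simulate_qpcr_run(tr, seed = r, copies = c(Entpd1 = 1000, Hprt = 1000))
      cv <- fit_standard_curve(run |>
        dplyr::filter(gene == "Entpd1", role == "standard") |>
        dplyr::transmute(copies = nominal_copies, ct))
      mean(quantify(run$ct[run$gene == "Entpd1" & run$role == "sample"], cv))
    }, numeric(1))
    sd(reps)
  }
  spreads <- vapply(c(0, 0.1, 0.5), spread_at, numeric(1))
  expect_true(all(diff(spreads) >= 0))

  # IOP: SD of the plateau estimate across replicates
  iop_spread <- function(iop_sd) {
    reps <- vapply(1:100, function(r) {
      tr <- quiet_truth(noise = list(iop_sd = iop_sd))
      s <- simulate_iop_course(tr, "OHT", "treated", seed = r)
      mean(s$value[grepl("^week([2-9]|1[0-2])$", s$timepoint)])
    }, numeric(1))
    sd(reps)
  }
  iop_spreads <- vapply(c(0, 1, 4), iop_spread, numeric(1))
  expect_true(all(diff(iop_spreads) >= 0))
})

test_that("cohort bookkeeping matches the configured design", {
  study <- simulate_study(tiny_config(), quiet_truth(), seed = 1)
  expect_equal(dplyr::n_distinct(study$waveforms$animal), 6)
  expect_equal(nrow(study$ground_truth), 12)  # both eyes
  expect_equal(attr(study$attrition, "attempted"), 6 + 41)
  # sham treated eyes carry no chronic elevation in truth
  gt <- study$ground_truth |>
    dplyr::filter(group == "sham", eye == "treated")
  expect_equal(gt$iop_plateau, gt$iop_baseline)
})
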