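toy_endpoints <- function(seed = 1, effect = 0.8) {
  withr::with_seed(seed, {
    animals <- c(paste0("O", 1:6), paste0("S", 1:5))
    grp <- rep(c("OHT", "sham"), c(6, 5))
    tidyr::expand_grid(
      tibble::tibble(animal = animals, group = grp),
      eye = c("treated", "control"),
      endpoint = c("rnfl", "pstr_amplitude")) |>
      dplyr::mutate(value = rnorm(dplyr::n(), 100, 3) *
                      ifelse(group == "OHT" & eye == "treated", effect, 1))
  })
}

test_that("report computes all three contrasts per endpoint", {
  rep_ <- build_report(toy_endpoints())
  expect_s3_class(rep_, "study_report")
  cmp <- rep_$comparisons
  expect_setequal(unique(cmp$contrast),
                  c("OHT_treated_vs_control", "sham_treated_vs_control",
                    "C-OHT_vs_C-Sham"))
  expect_equal(nrow(cmp), 2 * 3)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  oht <- cmp |> dplyr::filter(contrast == "OHT_treated_vs_control")
  expect_true(all(oht$test == "paired-t"))
  expect_true(all(oht$p_value < 0.05))
  ctl <- cmp |> dplyr::filter(contrast == "C-OHT_vs_C-Sham")
  expect_true(all(ctl$test == "unpaired-t"))
})

test_that("a missing endpoint value is flagged without harming the rest", {
  ep <- toy_endpoints() |>
    dplyr::filter(!(animal == "O1" & eye == "treated" & endpoint == "rnfl"))
  rep_ <- build_report(ep)
  expect_true(any(grepl("rnfl", rep_$flags)))
  r <- rep_$comparisons |>
    dplyr::filter(endpoint == "rnfl", contrast == "OHT_treated_vs_control")
  expect_equal(r$n, 5)  # one pair dropped
  other <- rep_$comparisons |>
    dplyr::filter(endpoint == "pstr_amplitude",
                  contrast == "OHT_treated_vs_control")
  expect_equal(other$n, 6)
})

test_that("tidiers and the optional Holm extension work", {
  rep_ <- build_report(toy_endpoints(), holm = TRUE)
  td <- tidy(rep_)
  expect_true("p_holm_extension" %in% names(td))
  expect_true(all(td$p_holm_extension >= td$p_value))
  g <- glance(rep_)
  expect_equal(g$n_comparisons, nrow(td))
  expect_error(build_report(dplyr::bind_rows(toy_endpoints(), toy_endpoints())),
               "Duplicate")
})

test_that("write/read round trip preserves study tables with headers", {
  dir <- withr::local_tempdir()
  study <- simulate_study(tiny_config(), study_truth(), seed = 4)
  write_study_tables(study, dir)
  first <- readLines(file.path(dir, "iop.csv"), n = 3)
  expect_true(all(grepl("^#", first)))
  expect_true(any(grepl("seed 4", first)))
  back <- read_study_tables(dir)
  expect_equal(as.data.frame(back$iop), as.data.frame(study$iop),
               tolerance = 1e-12)
  expect_equal(attr(back$attrition, "attempted"), attr(study$attrition, "attempted"))
  # analyze from files equals analyze in memory
  an_mem <- analyze_study(study)
  back$attrition <- study$attrition
  an_file <- analyze_study(back)
  expect_equal(an_file$report$comparisons$p_value,
               an_mem$report$comparisons$p_value, tolerance = 1e-4)
  expect_error(analyze_study(list(waveforms = study$waveforms)), "missing")
})

test_that("end-to-end decomposition recovers configured effect ratios", {
  # noiseless cohort: treated/control ratios recovered within 2%
  cfg <- tiny_config(n_oht = 2, n_sham = 2)
  study <- simulate_study(cfg, quiet_truth(), seed = 2)
  erg <- erg_decompose(study$waveforms)
  one <- function(eye_, col) {
    erg |> dplyr::filter(group == "OHT", animal == "OHT01",
                         eye == eye_) |> dplyr::pull({{ col }})
  }
  expect_equal(one("treated", rm_p3) / one("control", rm_p3), 0.85,
               tolerance = 0.02)
  expect_equal(one("treated", vmax) / one("control", vmax), 0.85,
               tolerance = 0.02)
  expect_equal(one("treated", pstr_amplitude) / one("control", pstr_amplitude),
               0.81, tolerance = 0.02)
})
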