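test_that("layer thickness over the peripapillary window", {
  b <- flat_boundaries(rnfl = 10, trt = 200)
  expect_equal(layer_thickness(b, "rnfl"), 10)
  expect_equal(layer_thickness(b, "trt"), 200)
  # linearly varying RNFL 8->12 um across each window averages to 10
  lin <- b |> dplyr::mutate(
    rnfl_post_um = ilm_um + 8 + 4 * (abs(position_um) - 100) / 700)
  expect_equal(layer_thickness(lin, "rnfl"), 10, tolerance = 1e-9)
  short <- b |> dplyr::filter(abs(position_um) <= 850)
  expect_error(layer_thickness(short, "rnfl", window_um = c(900, 1200)),
               "window")
  bad <- b |> dplyr::mutate(rnfl_post_um = ilm_um - 1)
  expect_error(layer_thickness(bad, "rnfl"), "ordering")
})

test_that("BMO width is the endpoint distance averaged over scans", {
  expect_equal(bmo_width(flat_bmo(width = 700)), 700)
  slanted <- flat_bmo(width = 700) |>
    dplyr::mutate(z_um = ifelse(side == "nasal", 20, 0))
  expect_equal(bmo_width(slanted), sqrt(700^2 + 20^2), tolerance = 1e-9)
  expect_equal(round(bmo_width(slanted), 1), 700.3)
  expect_error(bmo_width(flat_bmo()[1, ]), "two BMO endpoints")
})

test_that("MRT equals the brute-force minimum over ILM samples", {
  # worked example: ILM {(0,150),(50,145),(100,148)} from BMO at origin
  ilm <- tibble::tibble(scan_id = 1, position_um = c(0, 50, 100),
                        ilm_um = c(150, 145, 148),
                        rnfl_post_um = 160, bm_um = 400)
  bmo <- tibble::tibble(scan_id = 1, side = "temporal", x_um = 0, z_um = 0)
  expect_equal(minimum_rim_thickness(ilm, bmo), 150)
  # flat ILM 150 um above the endpoint
  b <- flat_boundaries(ilm = 100)
  ep <- flat_bmo(z = 250)
  expect_equal(minimum_rim_thickness(b, ep), 150)
  # oracle equivalence on random geometries
  for (s in 1:100) {
    g <- withr::with_seed(s, {
      n <- sample(5:40, 1)
      list(ilm = tibble::tibble(scan_id = 1,
                                position_um = sort(runif(n, -500, 500)),
                                ilm_um = runif(n, 80, 120),
                                rnfl_post_um = 130, bm_um = 400),
           bmo = tibble::tibble(scan_id = 1, side = "temporal",
                                x_um = runif(1, -300, 300),
                                z_um = runif(1, 150, 300)))
    })
    oracle <- Inf
    for (j in seq_len(nrow(g$ilm))) {
      oracle <- min(oracle, sqrt((g$ilm$position_um[j] - g$bmo$x_um)^2 +
                                   (g$ilm$ilm_um[j] - g$bmo$z_um)^2))
    }
    expect_equal(minimum_rim_thickness(g$ilm, g$bmo), oracle, tolerance = 1e-12)
  }
  expect_error(minimum_rim_thickness(b[0, ], ep), "ILM|ordering")
})

test_that("Doppler counting is exact, monotone in threshold, and conserved", {
  scan <- tibble::tibble(
    channel = rep(c("arterial", "venous"), c(220, 180)),
    value = c(runif_seeded <- NULL,
              withr::with_seed(3, c(runif(120, 0.6, 1), runif(100, 0, 0.3),
                                    runif(80, 0.6, 1), runif(100, 0, 0.3)))))
  res <- doppler_flow(scan)
  expect_equal(res$arterial, 120)
  expect_equal(res$venous, 80)
  expect_equal(res$total, 200)
  # raising a numeric threshold can only lower counts; total is conserved
  thrs <- seq(0, 1, by = 0.1)
  counts <- purrr::map(thrs, ~ doppler_flow(scan, threshold = .x))
  tot <- purrr::map_dbl(counts, "total")
  expect_true(all(diff(tot) <= 0))
  for (ct in counts) {
    expect_equal(ct$total, ct$arterial + ct$venous)
  }
  # exhaustive count oracle at a fixed threshold
  expect_equal(doppler_flow(scan, threshold = 0.5)$total,
               sum(scan$value > 0.5))
  expect_error(doppler_flow(scan[0, ]), "Empty")
})

test_that("pupil diameter averages the two meridians", {
  expect_equal(pupil_diameter(1900, 1900), 1900)
  expect_equal(pupil_diameter(1950, 1902), 1926)
  expect_error(pupil_diameter(0, 1900), "positive")
})

test_that("RGC density is count over field area", {
  # 290.62 um square field is 0.08446 mm^2
  expect_equal(rgc_density(298), 298 / 0.0844600, tolerance = 1e-4)
  expect_equal(round(rgc_density(298)), 3528)
  expect_equal(rgc_density(0), 0)
  expect_equal(rgc_density(596), 2 * rgc_density(298))
  expect_equal(rgc_density(298, 581.24, 290.62), rgc_density(298) / 2)
  expect_error(rgc_density(10, 0, 10), "area")
  expect_error(rgc_density(-1), "non-negative")
})

test_that("TRT is never below RNFL for valid boundary tables", {
  for (s in 1:20) {
    b <- withr::with_seed(s, {
      rnfl <- runif(1, 5, 20); extra <- runif(1, 50, 300)
      flat_boundaries(rnfl = rnfl, trt = rnfl + extra)
    })
    expect_gte(layer_thickness(b, "trt"), layer_thickness(b, "rnfl"))
  }
})
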