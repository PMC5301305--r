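# Shared fixtures: all synthetic inputs are built in code.

# ground truth with all stochastic terms silenced
quiet_truth <- function(...) {
  args <- list(...)
  noise <- utils::modifyList(
    list(erg_sd = 0, iop_sd = 0, ct_sd = 0, cv_animal = 0, cv_eye = 0,
         cv_gene_animal = 0, baseline_iop_sd = 0),
    if (is.null(args$noise)) list() else args$noise)
  args$noise <- noise
  do.call(study_truth, args)
}

# reduced energy grid that still spans the protocol range and contains
# the pSTR trio and two bright flashes
tiny_grid <- c(-6.35, -5.31, -5.01, -4.90, -4.31, -3.01, -1.61, 1.07, 2.07)

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_oht = 3, n_sham = 3, energy_grid = tiny_grid,
         n_qpcr = c(oht = 3, sham = 3), n_rgc = c(oht = 3, sham = 3)),
    list(...))
  do.call(cohort_config, args)
}

# flat OCT boundary fixture with known thicknesses
flat_boundaries <- function(rnfl = 12.3, trt = 230, n_scans = 2,
                            ilm = 100, pos = seq(-1000, 1000, by = 10)) {
  tidyr::expand_grid(scan_id = seq_len(n_scans), position_um = pos) |>
    dplyr::mutate(ilm_um = ilm, rnfl_post_um = ilm + rnfl,
                  ipl_um = ilm + rnfl + 30, bm_um = ilm + trt)
}

flat_bmo <- function(width = 700, z = 250, n_scans = 2) {
  tidyr::expand_grid(scan_id = seq_len(n_scans),
                     side = c("temporal", "nasal")) |>
    dplyr::mutate(x_um = ifelse(side == "temporal", -width / 2, width / 2),
                  z_um = z)
}

# noiseless IOP series via the generator
iop_series <- function(baseline = 14, delta = 5.7, spike = 38, tau = 2,
                       group = "OHT", eye = "treated") {
  tr <- quiet_truth(iop = list(baseline_mean = baseline, spike_peak = spike,
                               decay_tau = tau, plateau_delta = delta))
  simulate_iop_course(tr, group = group, eye = eye)
}

# exact standard-curve fixture: slope -3.32, intercept 36.64
exact_curve_points <- function() {
  tibble::tibble(copies = 10^(2:5), ct = c(30.00, 26.68, 23.36, 20.04))
}

# brute-force grid-search oracle over (RmP3, S, td): lowest sum of squares
# on the supplied fit data over an n_rm x n_s x n_td grid (the RmP3 axis
# is handled in closed form because the loss is quadratic in it,
# evaluated exactly at the grid values)
p3_grid_loss <- function(fit_data, n_rm = 50, n_s = 50, n_td = 10) {
  v <- fit_data$voltage_uV
  v_min <- min(v)
  rm_grid <- seq(1.5 * v_min, 0.5 * v_min, length.out = n_rm)
  s_grid <- 10^seq(1, 5, length.out = n_s)
  td_grid <- seq(0, 8, length.out = n_td)
  c0 <- sum(v^2)
  best <- Inf
  for (td in td_grid) {
    dt2 <- pmax((fit_data$time_ms - td) / 1000, 0)^2
    for (s in s_grid) {
      b <- 1 - exp(-fit_data$i * s * dt2)
      losses <- c0 - 2 * rm_grid * sum(v * b) + rm_grid^2 * sum(b^2)
      best <- min(best, min(losses))
    }
  }
  best
}

# pure-tone measurement of a zero-phase filter's gain
tone_gain <- function(filt, freq, fs = 4000, dur_s = 3) {
  t <- seq(0, dur_s, by = 1 / fs)
  y <- op_filtfilt(filt, sin(2 * pi * freq * t))
  mid <- seq(length(y) %/% 4, 3 * length(y) %/% 4)
  20 * log10(sqrt(mean(y[mid]^2)) / sqrt(0.5))
}
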