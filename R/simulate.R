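#' Ground truth for a simulated chronic ocular-hypertension study
#'
#' Bundles the per-eye generating parameters of every modality. Defaults
#' are the control-eye group means the study design targets: ERG
#' amplitudes/sensitivities typical of dark-adapted mouse recordings,
#' tonometry baseline ~14 mmHg with a post-surgical spike decaying to a
#' chronic plateau ~5-6 mmHg above baseline, peripapillary OCT
#' thicknesses, per-quadrant ganglion-cell densities, and
#' relative-to-Hprt transcript levels. Noise levels are stated here
#' explicitly (they are generator configuration, not literature values).
#'
#' @param erg Named list: `rm_p3` (uV, negative), `S` (m^2.cd^-1.s^-3),
#'   `td_ms`, `vmax` (uV), `k` (cd.s/m^2), `op_amplitude` (uV),
#'   `op_frequency` (Hz), `op_delay_ms`, `pstr_amplitude` (uV),
#'   `pstr_peak_ms`.
#' @param iop Named list: `baseline_mean`, `spike_peak`, `decay_tau`
#'   (days), `plateau_delta` (mmHg above baseline; 0 for eyes without
#'   chronic elevation).
#' @param morph Named list: `rnfl`, `trt`, `bmo`, `mrt` (um), `rgc`
#'   (named density vector, cells/mm^2), `doppler` (named pixel counts),
#'   `pupil_um`.
#' @param expr Named list: `hprt_copies`, `ratios` (named normalized
#'   levels per panel gene), `slope`, `intercept` (standard-curve
#'   parameters), `standard_copies`.
#' @param noise Named list: `erg_sd` (uV per sample, post sweep
#'   averaging), `iop_sd` (mmHg per tonometer reading), `ct_sd` (cycles
#'   per well), `cv_animal`, `cv_eye` (biological lognormal CVs),
#'   `cv_gene_animal`, `baseline_iop_sd`.
#' @return A validated list of class `study_truth`.
#' @export
study_truth <- function(erg = list(), iop = list(), morph = list(),
                        expr = list(), noise = list()) {
  merge_in <- function(defaults, user) utils::modifyList(defaults, user)
  out <- list(
    erg = merge_in(list(
      rm_p3 = -624, S = 10^2.63, td_ms = 3,
      vmax = 863, k = 10^-3.26,
      op_amplitude = 114, op_frequency = 110, op_delay_ms = 42,
      op_sigma_ms = 4,
      pstr_amplitude = 16, pstr_peak_ms = 110, pstr_sigma_ms = 15,
      pstr_k = 10^-4.6, pstr_ref_energy = -5.01,
      p2_peak_ms = 45, p2_shape = 8), erg),
    iop = merge_in(list(
      baseline_mean = 13.8, spike_peak = 38, decay_tau = 2.9,
      plateau_delta = 5.7), iop),
    morph = merge_in(list(
      rnfl = 12.3, trt = 230, bmo = 700, mrt = 150.4,
      rgc = c(superior = 3531, temporal = 3678,
              inferior = 3772, nasal = 3592),
      doppler = c(arterial = 2016, venous = 1344),
      pupil_um = 1926), morph),
    expr = merge_in(list(
      hprt_copies = 3200,
      ratios = c(P2x7 = 0.05, Adora3 = 0.02, Panx1 = 0.50,
                 Trpv4 = 0.10, Entpd1 = 0.28),
      slope = -3.322, intercept = 36.64,
      standard_copies = 10^(2:5)), expr),
    noise = merge_in(list(
      erg_sd = 1.5, iop_sd = 1.5, ct_sd = 0.08,
      cv_animal = 0.15, cv_eye = 0.06, cv_gene_animal = 0.08,
      baseline_iop_sd = 1.0), noise)
  )
  with(out$erg, {
    if (rm_p3 > 0) abort("Ground truth rm_p3 must be <= 0 (corneal-negative).")
    if (S <= 0 || vmax < 0 || k <= 0) abort("Ground truth S, vmax, k must be positive.")
  })
  with(out$iop, {
    if (plateau_delta < 0) abort("plateau_delta must be >= 0.")
    if (baseline_mean <= 0 || decay_tau <= 0) abort("IOP parameters must be positive.")
  })
  if (any(unlist(out$morph[c("rnfl", "trt", "bmo", "mrt")]) < 0) ||
      any(out$morph$rgc < 0)) {
    abort("Thickness and density means must be non-negative.")
  }
  if (out$expr$hprt_copies <= 0 || any(out$expr$ratios <= 0)) {
    abort("Copy-number means must be positive.")
  }
  structure(out, class = "study_truth")
}

#' Treated-eye effect multipliers for the ocular-hypertension group
#'
#' Ratios applied to the treated eye of OHT animals relative to its own
#' contralateral control. Defaults encode the chronic-IOP phenotype the
#' study design targets: moderate outer/inner retinal ERG deficits
#' (-15%), a larger ganglion-cell (pSTR) deficit (-19%), RNFL thinning
#' (-20%), mild rim thinning, quadrant-specific RGC loss (-8 to -17%),
#' Entpd1 upregulation (+11%), no change elsewhere.
#'
#' @param ... Named overrides.
#' @return Named list of multipliers.
#' @export
oht_effects <- function(...) {
  utils::modifyList(list(
    rm_p3 = 0.85, vmax = 0.85, op_amplitude = 0.91, pstr_amplitude = 0.81,
    S = 1, k = 1,
    rnfl = 0.80, trt = 1, bmo = 1, mrt = 0.954,
    rgc = c(superior = 0.834, temporal = 0.912,
            inferior = 0.901, nasal = 0.897),
    doppler = 1.056, pupil = 1,
    genes = c(P2x7 = 1, Adora3 = 1, Panx1 = 1, Trpv4 = 1, Entpd1 = 1.107),
    plateau_delta = 1
  ), list(...))
}

#' Configuration of a simulated two-group bilateral cohort
#'
#' @param n_oht,n_sham Animals per group (>= 2 each).
#' @param energy_grid Flash energies, log10 cd.s/m^2; must span
#'   -6.35 to 2.07 and include the pSTR analysis energies.
#' @param fs ERG sampling rate, Hz.
#' @param record_ms ERG record window `c(start, end)` in ms around flash
#'   onset; must cover the pSTR peak.
#' @param effects Treated-eye multipliers, see [oht_effects()].
#' @param n_qpcr,n_rgc Animals per group entering the qPCR and
#'   flat-mount subsets.
#' @param attrition Named complication counts preceding the study cohort.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_oht = 23, n_sham = 17,
                          energy_grid = c(-6.35, -5.31, -5.01, -4.90,
                                          -4.31, -3.61, -3.01, -2.31,
                                          -1.61, -0.81, 0.07, 1.07, 2.07),
                          fs = 4000, record_ms = c(-25, 250),
                          effects = oht_effects(),
                          n_qpcr = c(oht = 9, sham = 9),
                          n_rgc = c(oht = 12, sham = 8),
                          attrition = c(hyphema = 29, suture_failure = 12)) {
  if (n_oht < 2 || n_sham < 2) abort("Need at least 2 animals per group.")
  if (length(energy_grid) == 0) abort("Energy grid must be nonempty.")
  if (fs <= 0) abort("Sampling rate must be positive.")
  if (min(energy_grid) > -6.35 + 1e-9 || max(energy_grid) < 2.07 - 1e-9) {
    abort("Energy grid must span -6.35 to 2.07 log cd.s/m^2.")
  }
  structure(list(n_oht = n_oht, n_sham = n_sham,
                 energy_grid = sort(energy_grid), fs = fs,
                 record_ms = record_ms, effects = effects,
                 n_qpcr = n_qpcr, n_rgc = n_rgc, attrition = attrition),
            class = "cohort_config")
}

## --- component kernels ------------------------------------------------

p2_kernel <- function(t_ms, peak_ms, shape) {
  x <- pmax(t_ms, 0) / peak_ms
  ifelse(t_ms <= 0, 0, x^shape * exp(shape * (1 - x)))
}

op_wavelet <- function(t_ms, center_ms, sigma_ms, freq_hz) {
  exp(-(t_ms - center_ms)^2 / (2 * sigma_ms^2)) *
    cos(2 * pi * freq_hz * (t_ms - center_ms) / 1000)
}

gauss_bump <- function(t_ms, center_ms, sigma_ms) {
  exp(-(t_ms - center_ms)^2 / (2 * sigma_ms^2))
}

## saturating pSTR energy dependence, normalized to 1 at the reference
## (dim analysis) energy so `pstr_amplitude` is the bump height there
pstr_scale <- function(i, k, i_ref) (i / (i + k)) / (i_ref / (i_ref + k))

#' Simulate one eye's ERG intensity series
#'
#' Each waveform is the sum of a delayed-Gaussian P3, a gamma-shaped P2
#' transient whose amplitude follows the Naka-Rushton energy dependence,
#' a Gaussian-windowed oscillatory-potential wavelet riding the P2 rising
#' phase at bright energies, a small positive pSTR bump dominating at the
#' dim analysis energies, and white Gaussian noise.
#'
#' @param truth A [study_truth()] (its `$erg` and `$noise$erg_sd` are used).
#' @param config A [cohort_config()] (energy grid, sampling rate, record).
#' @param seed Integer seed; required whenever the noise SD is positive.
#' @param noise_sd Override of the waveform noise SD (uV).
#' @return Tibble `energy_log`, `time_ms`, `voltage_uV`.
#' @export
simulate_erg_family <- function(truth, config, seed = NULL,
                                noise_sd = truth$noise$erg_sd) {
  if (config$fs <= 0) abort("Sampling rate must be positive.")
  if (length(config$energy_grid) == 0) abort("Energy grid must be nonempty.")
  if (config$record_ms[2] < truth$erg$pstr_peak_ms) {
    abort("Record length does not cover the pSTR peak time.")
  }
  if (noise_sd > 0 && is.null(seed)) {
    abort("A seed is required when the waveform noise SD is positive.")
  }
  e <- truth$erg
  t_ms <- seq(config$record_ms[1], config$record_ms[2], by = 1000 / config$fs)
  grid <- tidyr::expand_grid(energy_log = config$energy_grid, time_ms = t_ms) |>
    mutate(i = to_linear_energy(.data$energy_log))
  v <- p3_model(grid$i, grid$time_ms, e$rm_p3, e$S, e$td_ms) +
    e$vmax * grid$i / (grid$i + e$k) *
      p2_kernel(grid$time_ms, e$p2_peak_ms, e$p2_shape) +
    e$op_amplitude * grid$i / (grid$i + e$k) *
      op_wavelet(grid$time_ms, e$op_delay_ms, e$op_sigma_ms, e$op_frequency) +
    e$pstr_amplitude *
      pstr_scale(grid$i, e$pstr_k, to_linear_energy(e$pstr_ref_energy)) *
      gauss_bump(grid$time_ms, e$pstr_peak_ms, e$pstr_sigma_ms)
  if (noise_sd > 0) {
    v <- v + withr::with_seed(seed, rnorm(length(v), 0, noise_sd))
  }
  grid |> transmute(.data$energy_log, .data$time_ms, voltage_uV = v)
}

#' Simulate one eye's longitudinal IOP course
#'
#' Five daily baseline values, the acute post-surgical spike (2 min, 1 h,
#' 3 h), days 1-3 decaying exponentially toward the chronic level, then
#' weekly values at the plateau. Treated OHT eyes plateau at
#' `baseline + plateau_delta`; control eyes stay at baseline; sham
#' treated eyes spike but revert to baseline from day 2 onward (suture
#' removed on day 2). Every timepoint is the mean of 10 simulated
#' tonometer readings.
#'
#' @param truth A [study_truth()].
#' @param group `"OHT"` or `"sham"`.
#' @param eye `"treated"` or `"control"`.
#' @param seed Integer seed (required when reading noise is positive).
#' @param baseline Optional per-animal baseline override, mmHg.
#' @return Tibble `timepoint`, `value`, `reading_1` .. `reading_10`.
#' @export
simulate_iop_course <- function(truth, group, eye = "treated", seed = NULL,
                                baseline = NULL) {
  if (!group %in% c("OHT", "sham")) abort(paste0("Unknown group label: ", group))
  if (!eye %in% c("treated", "control")) abort(paste0("Unknown eye label: ", eye))
  io <- truth$iop
  base <- baseline %||% io$baseline_mean
  tps <- iop_timepoints()
  t_days <- c(rep(NA, 5), 2 / 1440, 1 / 24, 3 / 24, 1, 2, 3, NA + 1:12)

  nominal <- vapply(seq_along(tps), function(j) {
    tp <- tps[j]
    if (is_baseline_tp(tp) || eye == "control") return(base)
    if (group == "OHT") {
      plateau <- base + io$plateau_delta
      if (grepl("^week", tp)) return(plateau)
      return(plateau + (io$spike_peak - plateau) * exp(-t_days[j] / io$decay_tau))
    }
    # sham treated: spike decays toward baseline; reverts fully from day 2
    if (tp %in% c("2min", "1h", "3h", "day1")) {
      return(base + (io$spike_peak - base) * exp(-t_days[j] / io$decay_tau))
    }
    base
  }, numeric(1))

  if (truth$noise$iop_sd > 0 && is.null(seed)) {
    abort("A seed is required when tonometer reading noise is positive.")
  }
  readings <- if (truth$noise$iop_sd > 0) {
    withr::with_seed(seed, matrix(rnorm(10 * length(nominal), rep(nominal, each = 10),
                                        truth$noise$iop_sd),
                                  ncol = 10, byrow = TRUE))
  } else {
    matrix(rep(nominal, 10), ncol = 10)
  }
  colnames(readings) <- paste0("reading_", 1:10)
  bind_cols(tibble(timepoint = tps, value = rowMeans(readings)),
            as_tibble(readings))
}

#' Simulate one eye's structural data: OCT boundaries, Doppler map, RGC fields
#'
#' Boundary traces are flat at the configured thicknesses so that the
#' morphometry module recovers them exactly; BMO endpoints are placed at
#' the configured opening width and rim distance; the Doppler map is a
#' bimodal pixel population whose supra-threshold counts equal the
#' configured flow counts; RGC field counts are Poisson with mean
#' density x field area.
#'
#' @param truth A [study_truth()] (its `$morph` is used, already scaled
#'   to the eye).
#' @param seed Integer seed for the stochastic parts (Doppler, counts).
#' @param n_scans Number of B-scans.
#' @return List with tibbles `boundaries`, `bmo_endpoints`, `doppler`,
#'   `rgc`, `pupil`.
#' @export
simulate_morphometry <- function(truth, seed = NULL, n_scans = 4) {
  m <- truth$morph
  if (any(unlist(m[c("rnfl", "trt", "bmo", "mrt")]) < 0)) {
    abort("Requested thicknesses must be non-negative.")
  }
  ilm_depth <- 100
  pos <- seq(-1000, 1000, by = 10)
  boundaries <- tidyr::expand_grid(scan_id = seq_len(n_scans), position_um = pos) |>
    mutate(ilm_um = ilm_depth,
           rnfl_post_um = ilm_depth + m$rnfl,
           ipl_um = ilm_depth + min(m$trt, m$rnfl + 30),
           bm_um = ilm_depth + m$trt)
  bmo_endpoints <- tidyr::expand_grid(scan_id = seq_len(n_scans),
                                      side = c("temporal", "nasal")) |>
    mutate(x_um = ifelse(.data$side == "temporal", -m$bmo / 2, m$bmo / 2),
           z_um = ilm_depth + m$mrt)

  sim_rand <- function(expr) {
    if (is.null(seed)) abort("A seed is required for the stochastic structural data.")
    withr::with_seed(seed, expr)
  }
  out <- sim_rand({
    doppler <- purrr::map(c("arterial", "venous"), function(ch) {
      n_flow <- rpois(1, m$doppler[[ch]])
      tibble(channel = ch,
             value = c(runif(n_flow, 0.6, 1), runif(4000, 0, 0.3)))
    }) |> list_rbind()
    rgc <- tidyr::expand_grid(quadrant = names(m$rgc),
                              eccentricity = c("central", "peripheral")) |>
      mutate(field_w_um = 290.62, field_h_um = 290.62,
             count = rpois(n(), m$rgc[.data$quadrant] *
                             .data$field_w_um * .data$field_h_um / 1e6))
    pupil <- tibble(horizontal_um = rnorm(1, m$pupil_um, 30),
                    vertical_um = rnorm(1, m$pupil_um, 30))
    list(doppler = doppler, rgc = rgc, pupil = pupil)
  })
  c(list(boundaries = boundaries, bmo_endpoints = bmo_endpoints), out)
}

#' Simulate a qPCR run for one sample
#'
#' Emits the four-point standard dilution Cts from the configured
#' log-linear curve and triplicate sample Cts for every panel gene, with
#' Gaussian per-well cycle noise.
#'
#' @param truth A [study_truth()] (its `$expr` and `$noise$ct_sd` are used).
#' @param seed Integer seed (required when `ct_sd > 0`).
#' @param copies Named vector of true absolute copies per gene (defaults
#'   to `ratios * hprt_copies` plus Hprt itself).
#' @return Tibble `gene`, `role`, `nominal_copies`, `ct` (standards have
#'   `nominal_copies`; samples have triplicate rows).
#' @export
simulate_qpcr_run <- function(truth, seed = NULL, copies = NULL) {
  ex <- truth$expr
  if (length(ex$standard_copies) < 2) {
    abort("Standard curves need at least 2 dilution points.")
  }
  if (is.null(copies)) {
    copies <- c(ex$ratios * ex$hprt_copies, Hprt = ex$hprt_copies)
  }
  ct_of <- function(cp) ex$intercept + ex$slope * log10(cp)
  std <- tidyr::expand_grid(gene = names(copies),
                            nominal_copies = ex$standard_copies) |>
    mutate(role = "standard", ct = ct_of(.data$nominal_copies))
  smp <- tidyr::expand_grid(gene = names(copies), rep = 1:3) |>
    mutate(role = "sample", nominal_copies = NA_real_,
           ct = unname(ct_of(copies[.data$gene]))) |>
    select(-"rep")
  out <- bind_rows(std, smp)
  if (truth$noise$ct_sd > 0) {
    if (is.null(seed)) abort("A seed is required when Ct noise is positive.")
    out$ct <- out$ct +
      withr::with_seed(seed, rnorm(nrow(out), 0, truth$noise$ct_sd))
  }
  out |> select("gene", "role", "nominal_copies", "ct")
}

## lognormal multiplicative factor with mean 1 and given CV
ln_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -s^2 / 2, s))
}

#' Simulate a complete two-group bilateral study
#'
#' Generates every input table the analysis modules consume (ERG
#' waveforms, tonometry, OCT boundaries and BMO endpoints, Doppler pixel
#' maps, RGC field counts, pupil widths, qPCR wells) for `n_oht` OHT and
#' `n_sham` sham animals, both eyes each, together with the per-eye
#' ground truth. Biological variability is a lognormal animal-level
#' factor shared by both eyes plus an independent eye-level factor;
#' treated OHT eyes additionally carry the configured effect multipliers.
#' Sham treated eyes experience the acute IOP spike only.
#'
#' @param config A [cohort_config()].
#' @param truth A [study_truth()] (control-eye generating means).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return List of class `simulated_study` with tibbles `waveforms`,
#'   `iop`, `oct`, `bmo`, `doppler`, `rgc`, `pupil`, `qpcr`,
#'   `ground_truth`, plus `config`, `attrition`, and `seed`.
#' @export
simulate_study <- function(config = cohort_config(), truth = study_truth(),
                           seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  eff <- config$effects
  animals <- bind_rows(
    tibble(animal = sprintf("OHT%02d", seq_len(config$n_oht)), group = "OHT"),
    tibble(animal = sprintf("SHAM%02d", seq_len(config$n_sham)), group = "sham"))

  plan <- withr::with_seed(seed, {
    n_a <- nrow(animals)
    fam <- animals |>
      mutate(f_erg = ln_factor(n_a, truth$noise$cv_animal),
             f_morph = ln_factor(n_a, truth$noise$cv_animal),
             f_rgc = ln_factor(n_a, truth$noise$cv_animal / 2),
             f_flow = ln_factor(n_a, truth$noise$cv_animal / 2),
             iop_base = rnorm(n_a, truth$iop$baseline_mean,
                              truth$noise$baseline_iop_sd))
    gene_fac <- tidyr::expand_grid(animal = animals$animal,
                                   gene = names(truth$expr$ratios)) |>
      mutate(f_gene = ln_factor(n(), truth$noise$cv_gene_animal))
    eyes <- tidyr::expand_grid(fam, eye = c("treated", "control")) |>
      mutate(g_erg = ln_factor(n(), truth$noise$cv_eye),
             g_morph = ln_factor(n(), truth$noise$cv_eye),
             g_rgc = ln_factor(n(), truth$noise$cv_eye / 2),
             g_flow = ln_factor(n(), truth$noise$cv_eye),
             g_rna = ln_factor(n(), 0.10),
             eye_seed = sample.int(.Machine$integer.max %/% 2, n()))
    list(eyes = eyes, gene_fac = gene_fac)
  })
  eyes <- plan$eyes

  per_eye <- purrr::map(seq_len(nrow(eyes)), function(r) {
    row <- eyes[r, ]
    oht_treated <- row$group == "OHT" && row$eye == "treated"
    e_mul <- if (oht_treated) eff else
      list(rm_p3 = 1, vmax = 1, op_amplitude = 1, pstr_amplitude = 1,
           S = 1, k = 1, rnfl = 1, trt = 1, bmo = 1, mrt = 1,
           rgc = setNames(rep(1, length(truth$morph$rgc)),
                          names(truth$morph$rgc)),
           doppler = if (row$group == "sham" && row$eye == "treated") 1.018 else 1,
           pupil = 1,
           genes = setNames(rep(1, length(truth$expr$ratios)),
                            names(truth$expr$ratios)),
           plateau_delta = 1)
    flow_base <- if (row$group == "sham") 2707 else sum(truth$morph$doppler)
    flow_split <- truth$morph$doppler / sum(truth$morph$doppler)

    eye_truth <- truth
    eye_truth$erg$rm_p3 <- truth$erg$rm_p3 * e_mul$rm_p3 * row$f_erg * row$g_erg
    eye_truth$erg$vmax <- truth$erg$vmax * e_mul$vmax * row$f_erg * row$g_erg
    eye_truth$erg$op_amplitude <-
      truth$erg$op_amplitude * e_mul$op_amplitude * row$f_erg * row$g_erg
    eye_truth$erg$pstr_amplitude <-
      truth$erg$pstr_amplitude * e_mul$pstr_amplitude * row$f_erg * row$g_erg
    eye_truth$erg$S <- truth$erg$S * e_mul$S
    eye_truth$erg$k <- truth$erg$k * e_mul$k
    eye_truth$iop$plateau_delta <-
      if (oht_treated) truth$iop$plateau_delta * e_mul$plateau_delta else 0
    eye_truth$morph$rnfl <- truth$morph$rnfl * e_mul$rnfl * row$f_morph * row$g_morph
    eye_truth$morph$trt <- truth$morph$trt * e_mul$trt * row$f_morph * row$g_morph
    eye_truth$morph$bmo <- truth$morph$bmo * e_mul$bmo
    eye_truth$morph$mrt <- truth$morph$mrt * e_mul$mrt * row$f_morph * row$g_morph
    eye_truth$morph$rgc <-
      truth$morph$rgc * e_mul$rgc[names(truth$morph$rgc)] * row$f_rgc * row$g_rgc
    eye_truth$morph$doppler <-
      flow_base * flow_split * e_mul$doppler * row$f_flow * row$g_flow
    eye_truth$morph$pupil_um <- truth$morph$pupil_um * e_mul$pupil

    gene_f <- plan$gene_fac |> filter(.data$animal == row$animal)
    gene_mult <- setNames(gene_f$f_gene, gene_f$gene)
    true_ratios <- truth$expr$ratios *
      e_mul$genes[names(truth$expr$ratios)] * gene_mult[names(truth$expr$ratios)]
    hprt_eye <- truth$expr$hprt_copies * row$g_rna  # sample RNA scale
    copies <- c(true_ratios * hprt_eye, Hprt = hprt_eye)

    id <- tibble(animal = row$animal, eye = row$eye, group = row$group)
    sim_erg <- simulate_erg_family(eye_truth, config, seed = row$eye_seed)
    sim_iop <- simulate_iop_course(eye_truth, group = row$group, eye = row$eye,
                                   seed = row$eye_seed + 1,
                                   baseline = row$iop_base)
    sim_morph <- simulate_morphometry(eye_truth, seed = row$eye_seed + 2)

    a_idx <- as.integer(sub("^[A-Za-z]+", "", row$animal))
    in_qpcr <- a_idx <= config$n_qpcr[[tolower(row$group)]]
    in_rgc <- a_idx <= config$n_rgc[[tolower(row$group)]]
    sim_qpcr <- if (in_qpcr) {
      simulate_qpcr_run(eye_truth, seed = row$eye_seed + 3, copies = copies) |>
        mutate(run_id = paste0("run_", .data$gene))
    }
    list(
      waveforms = bind_cols(id[rep(1, nrow(sim_erg)), ], sim_erg),
      iop = bind_cols(id[rep(1, nrow(sim_iop)), ], sim_iop),
      oct = bind_cols(id[rep(1, nrow(sim_morph$boundaries)), ], sim_morph$boundaries),
      bmo = bind_cols(id[rep(1, nrow(sim_morph$bmo_endpoints)), ],
                      sim_morph$bmo_endpoints),
      doppler = bind_cols(id[rep(1, nrow(sim_morph$doppler)), ], sim_morph$doppler),
      rgc = if (in_rgc) bind_cols(id[rep(1, nrow(sim_morph$rgc)), ], sim_morph$rgc),
      pupil = bind_cols(id, sim_morph$pupil),
      qpcr = if (in_qpcr) bind_cols(id[rep(1, nrow(sim_qpcr)), ], sim_qpcr),
      ground_truth = bind_cols(
        id,
        tibble(rm_p3 = eye_truth$erg$rm_p3, S = eye_truth$erg$S,
               td_ms = eye_truth$erg$td_ms, vmax = eye_truth$erg$vmax,
               k = eye_truth$erg$k,
               op_amplitude = eye_truth$erg$op_amplitude,
               pstr_amplitude = eye_truth$erg$pstr_amplitude,
               iop_baseline = row$iop_base,
               iop_plateau = row$iop_base + eye_truth$iop$plateau_delta,
               rnfl = eye_truth$morph$rnfl, trt = eye_truth$morph$trt,
               bmo = eye_truth$morph$bmo, mrt = eye_truth$morph$mrt),
        as_tibble(as.list(setNames(eye_truth$morph$rgc,
                                   paste0("rgc_", names(eye_truth$morph$rgc))))),
        as_tibble(as.list(setNames(true_ratios,
                                   paste0("expr_", names(true_ratios))))))
    )
  })

  gather <- function(name) {
    purrr::map(per_eye, name) |> purrr::compact() |> list_rbind()
  }
  structure(list(
    waveforms = gather("waveforms"), iop = gather("iop"),
    oct = gather("oct"), bmo = gather("bmo"), doppler = gather("doppler"),
    rgc = gather("rgc"), pupil = gather("pupil"), qpcr = gather("qpcr"),
    ground_truth = gather("ground_truth"),
    config = config, seed = seed,
    attrition = attrition_summary(
      attempted = config$n_oht + config$n_sham + sum(config$attrition),
      successes = config$n_oht + config$n_sham,
      causes = config$attrition)
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated OHT study (seed %d): %d OHT + %d sham animals, both eyes\n",
              x$seed, x$config$n_oht, x$config$n_sham))
  cat(sprintf("  %d waveform samples, %d IOP timepoints, %d qPCR wells\n",
              nrow(x$waveforms), nrow(x$iop), nrow(x$qpcr)))
  invisible(x)
}
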