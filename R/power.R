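#' Replicate simulation study of detection and false-positive behavior
#'
#' Simulates `n_rep` full cohorts at the configured effect sizes,
#' analyzes each end-to-end, and collects the paired treated-vs-control
#' p-values within the OHT group (power: true effects present) and
#' within the sham group (type-I behavior: no chronic effect simulated),
#' for a set of key endpoints.
#'
#' @param n_rep Number of replicate cohorts.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param config,truth Passed to [simulate_study()].
#' @param endpoints Endpoints extracted from each replicate's report.
#' @return Tibble `rep`, `endpoint`, `contrast`, `p_value`,
#'   `pct_ratio_of_means`.
#' @export
run_replicate_study <- function(n_rep = 20, seed = 1,
                                config = cohort_config(),
                                truth = study_truth(),
                                endpoints = c("pstr_amplitude",
                                              "p3_amplitude", "vmax",
                                              "rnfl", "expr_Entpd1")) {
  purrr::map(seq_len(n_rep), function(r) {
    study <- simulate_study(config, truth, seed = seed + r)
    an <- analyze_study(study)
    an$report$comparisons |>
      filter(.data$endpoint %in% endpoints,
             .data$contrast %in% c("OHT_treated_vs_control",
                                   "sham_treated_vs_control")) |>
      select("endpoint", "contrast", "p_value", "pct_ratio_of_means") |>
      mutate(rep = r, .before = 1)
  }) |> list_rbind()
}

#' Summarize a replicate study into power and false-positive rates
#'
#' @param reps Output of [run_replicate_study()].
#' @param alpha Significance level.
#' @return List with `power` (per-endpoint fraction of replicates whose
#'   OHT contrast is significant), `sham_fp_rate` (pooled fraction of
#'   significant sham contrasts across endpoints and replicates), and
#'   `mean_pct_change` (per-endpoint mean OHT percent change).
#' @export
summarize_replicates <- function(reps, alpha = 0.05) {
  oht <- reps |> filter(.data$contrast == "OHT_treated_vs_control")
  sham <- reps |> filter(.data$contrast == "sham_treated_vs_control")
  list(
    power = oht |> group_by(.data$endpoint) |>
      summarise(power = mean(.data$p_value < alpha), .groups = "drop"),
    sham_fp_rate = mean(sham$p_value < alpha),
    mean_pct_change = oht |> group_by(.data$endpoint) |>
      summarise(pct = mean(.data$pct_ratio_of_means), .groups = "drop")
  )
}
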