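#' Decompose one eye's intensity series into P3, P2, OP and pSTR measures
#'
#' Runs the full functional-analysis chain in order: (1) ensemble
#' delayed-Gaussian P3 fit on the brightest a-waves; (2) P3 subtraction to
#' derive per-energy P2 waveforms and a Naka-Rushton fit of their
#' amplitude-energy relation; (3) oscillatory-potential extraction from
#' the brightest-flash P2 trace; (4) pSTR measurement at the dim analysis
#' energies. Stage failures are re-signaled with the stage named.
#'
#' @param series Data frame for one eye: `energy_log`, `time_ms`,
#'   `voltage_uV` across the energy grid.
#' @param n_bright,p3_window_ms Passed to [fit_p3()].
#' @param p2_window_ms Passed to [measure_p2_amplitude()].
#' @param op_band,op_window_ms,op_filter Passed to [extract_ops()].
#' @param pstr_energies,pstr_window_ms Passed to [measure_pstr()].
#' @return An object of class `erg_decomposition`: components `p3`
#'   (`p3_fit`), `p2` (`nr_fit`), `ops` (`op_result`), `pstr`
#'   (`str_result`), plus the per-energy P2 amplitude table.
#' @export
erg_decompose_eye <- function(series, n_bright = 2, p3_window_ms = NULL,
                              p2_window_ms = c(0, 150),
                              op_band = c(50, 180), op_window_ms = c(10, 60),
                              op_filter = NULL,
                              pstr_energies = c(-5.31, -5.01, -4.90),
                              pstr_window_ms = c(80, 160)) {
  if (nrow(series) == 0) abort("Empty intensity series.")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("ERG decomposition failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  p3 <- stage("P3", fit_p3(series, n_bright = n_bright, window_ms = p3_window_ms))
  p2_waves <- stage("P2", derive_p2(series, p3))
  amps <- stage("P2", {
    p2_waves |>
      group_by(.data$energy_log) |>
      group_modify(~ tibble(amplitude_uV = measure_p2_amplitude(.x, p2_window_ms))) |>
      ungroup()
  })
  p2 <- stage("P2", fit_naka_rushton(amps))
  brightest <- p2_waves |> filter(.data$energy_log == max(.data$energy_log))
  ops <- stage("OPs", extract_ops(brightest, band = op_band,
                                  window_ms = op_window_ms, filt = op_filter))
  pstr <- stage("pSTR", measure_pstr(series, energies = pstr_energies,
                                     window_ms = pstr_window_ms))
  structure(list(p3 = p3, p2 = p2, ops = ops, pstr = pstr,
                 p2_amplitudes = amps),
            class = "erg_decomposition")
}

#' @export
print.erg_decomposition <- function(x, ...) {
  print(x$p3); print(x$p2); print(x$ops); print(x$pstr)
  invisible(x)
}

#' @rdname erg_decompose_eye
#' @param x An `erg_decomposition` object.
#' @param ... Unused.
#' @method tidy erg_decomposition
#' @export
tidy.erg_decomposition <- function(x, ...) {
  tibble(
    rm_p3 = x$p3$rm_p3, log_S = x$p3$log_S, td_ms = x$p3$td_ms,
    p3_residual_rms = x$p3$residual_rms,
    vmax = x$p2$vmax, k = x$p2$k, p2_log_sensitivity = x$p2$log_sensitivity,
    op_amplitude = x$ops$op_amplitude, op_implicit_ms = x$ops$op_implicit_ms,
    pstr_amplitude = x$pstr$pstr_amplitude,
    pstr_implicit_ms = x$pstr$pstr_implicit_ms
  )
}

#' Decompose every eye of a cohort waveform table
#'
#' Tidy driver over [erg_decompose_eye()]: expects the long waveform
#' format with identity columns and returns one row of fitted parameters
#' per eye. The OP band-pass filter is designed once and shared.
#'
#' @param waveforms Long data frame: `animal`, `eye`, `group`,
#'   `energy_log`, `time_ms`, `voltage_uV`.
#' @param ... Passed to [erg_decompose_eye()].
#' @return Tibble, one row per (animal, eye) with all ERG endpoints.
#' @export
erg_decompose <- function(waveforms, ...) {
  need <- c("animal", "eye", "group")
  if (!all(need %in% names(waveforms))) {
    abort("Cohort waveform table needs columns animal, eye, group.")
  }
  dt <- sampling_interval(waveforms$time_ms)
  dots <- list(...)
  if (is.null(dots$op_filter)) {
    band <- dots$op_band %||% c(50, 180)
    dots$op_filter <- op_bandpass(band, fs = 1000 / dt)
  }
  waveforms |>
    group_by(.data$animal, .data$eye, .data$group) |>
    group_modify(function(df, key) {
      tidy(do.call(erg_decompose_eye, c(list(series = df), dots)))
    }) |>
    ungroup()
}
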