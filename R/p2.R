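#' Derive the P2 (ON-bipolar) waveform by subtracting the fitted P3
#'
#' The b-wave is the sum of the photoreceptoral P3 and the post-receptoral
#' P2. Subtracting the modeled P3 (evaluated on the waveform's own time
#' grid at its flash energy) exposes the putative P2. The additive
#' identity `raw = P3 + P2` holds exactly by construction.
#'
#' @param waveform Data frame with columns `energy_log`, `time_ms`,
#'   `voltage_uV` (one or more energies for one eye).
#' @param fit A [fit_p3()] result for the same eye.
#' @return The input tibble with `voltage_uV` replaced by the P2 residual
#'   and the modeled P3 retained in `p3_uV`.
#' @export
derive_p2 <- function(waveform, fit) {
  if (!inherits(fit, "p3_fit")) abort("`fit` must be a `p3_fit` object.")
  if (!all(is.finite(c(fit$rm_p3, fit$S, fit$td_ms)))) {
    abort("P3 fit parameters are not finite.")
  }
  check_waveforms(waveform)
  dt <- sampling_interval(waveform$time_ms)
  dt_fit <- sampling_interval(fit$fit_data$time_ms)
  if (abs(dt - dt_fit) > 1e-6 * dt_fit) {
    abort("Time-grid mismatch between waveform and the P3 fit window.")
  }
  waveform |>
    group_by(.data$energy_log) |>
    mutate(voltage_uV = baseline_correct(.data$time_ms, .data$voltage_uV)) |>
    ungroup() |>
    mutate(
      p3_uV = p3_model(to_linear_energy(.data$energy_log), .data$time_ms,
                       fit$rm_p3, fit$S, fit$td_ms),
      voltage_uV = .data$voltage_uV - .data$p3_uV
    ) |>
    as_tibble()
}

#' Measure P2 amplitude
#'
#' Maximum positive excursion from the pre-stimulus baseline within the
#' post-stimulus window. A trace that never goes above baseline scores 0.
#'
#' @param p2 Data frame with `time_ms`, `voltage_uV` for a single
#'   baseline-corrected trace.
#' @param window_ms Post-stimulus search window, ms.
#' @return Amplitude in uV (>= 0).
#' @export
measure_p2_amplitude <- function(p2, window_ms = c(0, 150)) {
  v <- baseline_correct(p2$time_ms, p2$voltage_uV)
  post <- p2$time_ms > window_ms[1] & p2$time_ms <= window_ms[2]
  if (!any(post)) abort("Empty post-stimulus window.")
  max(0, max(v[post]))
}

#' Fit the Naka-Rushton (hyperbolic) intensity-response function
#'
#' Models P2 amplitude versus flash energy with the classical
#' agonist-receptor hyperbola \eqn{V(i) = V_{max} i / (i + k)}, where
#' \eqn{V_{max}} is the saturated amplitude and \eqn{k} the
#' semi-saturation energy (the energy at which amplitude is exactly
#' `Vmax / 2`). Sensitivity is reported as `log10(1/k)`.
#'
#' @param amplitudes Data frame with columns `energy_log` (log10 cd.s/m^2)
#'   and `amplitude_uV`.
#' @return An object of class `nr_fit` with `vmax` (uV), `k` (cd.s/m^2),
#'   `log_sensitivity`, residual RMS, and a `spanning` flag that is FALSE
#'   when the fitted `k` falls more than 10x outside the sampled energy
#'   range (the data then do not constrain the hyperbola).
#' @export
fit_naka_rushton <- function(amplitudes) {
  need <- c("energy_log", "amplitude_uV")
  if (!all(need %in% names(amplitudes))) {
    abort("`amplitudes` needs columns energy_log, amplitude_uV.")
  }
  amplitudes <- amplitudes |> arrange(.data$energy_log)
  if (length(unique(amplitudes$energy_log)) < 3) {
    abort("Naka-Rushton fit needs >= 3 distinct energies.")
  }
  i <- to_linear_energy(amplitudes$energy_log)
  a <- amplitudes$amplitude_uV

  loss <- function(par) {
    vmax <- par[1]; k <- 10^par[2]
    sum((a - vmax * i / (i + k))^2)
  }
  # heuristics: Vmax from max amplitude, k from energy nearest half-max
  a_max <- max(a)
  if (a_max <= 0) abort("All amplitudes are non-positive; nothing to fit.")
  k0 <- i[which.min(abs(a - a_max / 2))]
  init <- c(a_max, log10(k0))
  best <- optim(init, loss, method = "L-BFGS-B",
                lower = c(1e-9, -9), upper = c(10 * a_max, 4),
                control = list(maxit = 500, parscale = c(a_max, 1)))
  pol <- optim(best$par, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (is.finite(pol$value) && pol$value < best$value && pol$par[1] > 0) best <- pol

  vmax <- best$par[1]; k <- 10^best$par[2]
  fitted <- vmax * i / (i + k)
  spanning <- k >= min(i) / 10 && k <= max(i) * 10
  if (!spanning) {
    warn("Fitted semi-saturation k lies > 10x outside the sampled energy range.")
  }
  structure(list(
    vmax = vmax, k = k, log_sensitivity = log10(1 / k),
    residual_rms = sqrt(mean((a - fitted)^2)),
    loss = best$value, spanning = spanning,
    amplitudes = as_tibble(amplitudes) |> mutate(i = i, fitted = fitted)
  ), class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("Naka-Rushton intensity-response fit\n")
  cat(sprintf("  Vmax = %.1f uV   k = %.3g cd.s/m^2   log sensitivity = %.2f\n",
              x$vmax, x$k, x$log_sensitivity))
  cat(sprintf("  residual RMS %.2f uV over %d energies%s\n", x$residual_rms,
              nrow(x$amplitudes),
              if (x$spanning) "" else "  [k outside sampled range]"))
  invisible(x)
}

#' @rdname fit_naka_rushton
#' @param x An `nr_fit` object.
#' @param ... Unused.
#' @method tidy nr_fit
#' @export
tidy.nr_fit <- function(x, ...) {
  tibble(term = c("vmax", "k", "log_sensitivity"),
         estimate = c(x$vmax, x$k, x$log_sensitivity),
         unit = c("uV", "cd.s/m^2", "log10 m^2.cd^-1.s^-3"))
}

#' @rdname fit_naka_rushton
#' @method glance nr_fit
#' @export
glance.nr_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, loss = x$loss,
         n_energies = nrow(x$amplitudes), spanning = x$spanning)
}

#' @method autoplot nr_fit
#' @export
autoplot.nr_fit <- function(object, ...) {
  grid <- tibble(energy_log = seq(min(object$amplitudes$energy_log),
                                  max(object$amplitudes$energy_log),
                                  length.out = 200)) |>
    mutate(i = to_linear_energy(.data$energy_log),
           fitted = object$vmax * .data$i / (.data$i + object$k))
  ggplot2::ggplot(object$amplitudes,
                  ggplot2::aes(x = .data$energy_log, y = .data$amplitude_uV)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::labs(x = "Flash energy (log cd.s/m^2)", y = "P2 amplitude (uV)",
                  title = "Naka-Rushton intensity-response fit") +
    ggplot2::theme_minimal()
}
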