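#' Ensemble fit of the delayed-Gaussian P3 model to bright-flash a-waves
#'
#' Fits a single (RmP3, S, td) triple jointly, by least squares, to the
#' leading edges of the a-waves evoked by the brightest flashes of an
#' intensity series. Only the leading edge (flash onset to just past the
#' a-wave trough) is modeled; beyond the trough the post-receptoral P2
#' dominates and the model no longer applies.
#'
#' @param waves Data frame for one eye with columns `energy_log`
#'   (log10 cd.s/m^2), `time_ms`, `voltage_uV`. A pre-stimulus segment
#'   (t <= 0) is expected for baseline correction.
#' @param n_bright Number of brightest energies in the ensemble (default 2).
#' @param energies Optional explicit vector of log energies to use instead
#'   of the `n_bright` brightest.
#' @param window_ms Fit window `c(lo, hi)` in ms. Default `NULL` sets it
#'   from flash onset to 1 ms past the a-wave trough of the brightest flash.
#' @param trough_search_ms Window searched for the a-wave trough, ms.
#' @return An object of class `p3_fit`: fitted `rm_p3` (uV), `S`
#'   (m^2.cd^-1.s^-3), `log_S`, `td_ms`, the fit window, residual RMS, and
#'   the (baseline-corrected) samples used.
#' @seealso [p3_model()], [derive_p2()], [tidy.p3_fit()]
#' @export
fit_p3 <- function(waves, n_bright = 2, energies = NULL,
                   window_ms = NULL, trough_search_ms = c(0, 50)) {
  check_waveforms(waves)
  waves <- waves |>
    group_by(.data$energy_log) |>
    mutate(voltage_uV = baseline_correct(.data$time_ms, .data$voltage_uV)) |>
    ungroup()

  grid <- sort(unique(waves$energy_log))
  if (is.null(energies)) {
    if (length(grid) < n_bright || n_bright < 2) {
      abort("Ensemble P3 fit needs at least 2 bright-flash waveforms.")
    }
    energies <- tail(grid, n_bright)
  } else if (length(energies) < 2 || !all(energies %in% grid)) {
    abort("`energies` must name at least 2 energies present in the series.")
  }
  sel <- waves |> filter(.data$energy_log %in% energies)

  brightest <- sel |> filter(.data$energy_log == max(.data$energy_log))
  if (is.null(window_ms)) {
    inwin <- brightest$time_ms > trough_search_ms[1] &
      brightest$time_ms <= trough_search_ms[2]
    if (!any(inwin)) abort("Trough search window contains no samples.")
    v <- brightest$voltage_uV[inwin]
    if (min(v) > -1e-6) {
      abort("No negative a-wave deflection detected; cannot fit P3.")
    }
    trough_t <- brightest$time_ms[inwin][which.min(v)]
    window_ms <- c(0, trough_t + 1)
  }

  fitdat <- sel |>
    filter(.data$time_ms >= window_ms[1], .data$time_ms <= window_ms[2]) |>
    mutate(i = to_linear_energy(.data$energy_log))
  if (nrow(fitdat) == 0) abort("P3 fit window contains no samples.")

  loss <- function(par) {
    r <- fitdat$voltage_uV -
      p3_model(fitdat$i, fitdat$time_ms, par[1], 10^par[2], par[3])
    sum(r^2)
  }

  v_min <- min(fitdat$voltage_uV)
  if (v_min > -1e-6) abort("Selected waveforms carry no negative deflection in the fit window.")
  td_hi <- max(0.5, min(10, window_ms[2] - 0.25))
  init <- c(v_min, 3, min(3, td_hi))
  lower <- c(4 * v_min, -2, 0)
  upper <- c(-1e-9, 8, td_hi)

  run <- function(p0) {
    tryCatch(
      optim(p0, loss, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500,
                           parscale = c(abs(v_min), 1, 1))),
      error = function(e) NULL)
  }
  best <- run(init)
  # multi-start on failure or poor convergence
  if (is.null(best) || !is.finite(best$value)) {
    starts <- list(
      c(v_min * 1.2, 2.5, 1), c(v_min * 0.9, 3.5, 2),
      c(v_min, 2, 4), c(v_min * 1.1, 4, 0.5), c(v_min, 3, td_hi / 2))
    for (s in starts) {
      cand <- run(s)
      if (!is.null(cand) && is.finite(cand$value) &&
          (is.null(best) || cand$value < best$value)) best <- cand
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    abort("P3 fit diverged (non-finite loss); check the input waveforms.")
  }
  # local polish from the box solution
  pol <- tryCatch(
    optim(best$par, loss, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value &&
      pol$par[1] <= 0 && pol$par[3] >= 0 && pol$par[3] < 10) best <- pol

  fitted <- p3_model(fitdat$i, fitdat$time_ms, best$par[1], 10^best$par[2], best$par[3])
  structure(list(
    rm_p3 = best$par[1],
    S = 10^best$par[2],
    log_S = best$par[2],
    td_ms = best$par[3],
    window_ms = window_ms,
    energies = energies,
    loss = best$value,
    residual_rms = sqrt(mean((fitdat$voltage_uV - fitted)^2)),
    n_obs = nrow(fitdat),
    convergence = best$convergence,
    fit_data = as_tibble(fitdat) |> mutate(fitted = fitted)
  ), class = "p3_fit")
}

#' @export
print.p3_fit <- function(x, ...) {
  cat("Delayed-Gaussian P3 ensemble fit\n")
  cat(sprintf("  RmP3 = %.1f uV   S = %.1f m^2.cd^-1.s^-3 (log S = %.2f)   td = %.2f ms\n",
              x$rm_p3, x$S, x$log_S, x$td_ms))
  cat(sprintf("  window %.1f-%.1f ms, %d samples over energies {%s}, residual RMS %.2f uV\n",
              x$window_ms[1], x$window_ms[2], x$n_obs,
              paste(format(x$energies), collapse = ", "), x$residual_rms))
  invisible(x)
}

#' @rdname fit_p3
#' @param x A `p3_fit` object.
#' @param ... Unused.
#' @method tidy p3_fit
#' @export
tidy.p3_fit <- function(x, ...) {
  tibble(term = c("rm_p3", "S", "log_S", "td_ms"),
         estimate = c(x$rm_p3, x$S, x$log_S, x$td_ms),
         unit = c("uV", "m^2.cd^-1.s^-3", "log10 m^2.cd^-1.s^-3", "ms"))
}

#' @rdname fit_p3
#' @method glance p3_fit
#' @export
glance.p3_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, loss = x$loss, n_obs = x$n_obs,
         n_energies = length(x$energies), convergence = x$convergence)
}

#' @method autoplot p3_fit
#' @export
autoplot.p3_fit <- function(object, ...) {
  ggplot2::ggplot(object$fit_data,
                  ggplot2::aes(x = .data$time_ms, group = .data$energy_log)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$voltage_uV), size = 0.6,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = factor(.data$energy_log))) +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (uV)",
                  colour = "log energy",
                  title = "P3 leading-edge ensemble fit") +
    ggplot2::theme_minimal()
}
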