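#' Convert log flash energy to linear energy
#'
#' Flash energies are conventionally reported on a log10 scale
#' (log cd.s/m^2); the phototransduction and Naka-Rushton models take
#' linear energy (cd.s/m^2).
#'
#' @param energy_log Numeric vector of flash energies in log10 cd.s/m^2.
#' @return Numeric vector of linear flash energies in cd.s/m^2.
#' @examples
#' to_linear_energy(0)      # 1
#' to_linear_energy(2.07)   # 117.5
#' @export
to_linear_energy <- function(energy_log) {
  if (!is.numeric(energy_log) || any(!is.finite(energy_log))) {
    abort("`energy_log` must be finite numeric.")
  }
  10^energy_log
}

#' Delayed-Gaussian photoreceptor (P3) model
#'
#' Leading-edge model of the rod photoreceptor response:
#' \deqn{P3(i, t) = Rm_{P3} \{1 - \exp[-i S (t - t_d)^2]\}, \quad t > t_d}
#' and 0 for \eqn{t \le t_d}. Time enters the exponent in seconds; the
#' function takes milliseconds for convenience. `rm_p3` is the saturated
#' (maximal) amplitude and is negative by convention (corneal-negative
#' a-wave); `S` is the sensitivity in m^2.cd^-1.s^-3; `td_ms` a short
#' transduction delay.
#'
#' @param i Linear flash energy, cd.s/m^2 (scalar or vector recycled
#'   against `t_ms`).
#' @param t_ms Time from flash onset, ms.
#' @param rm_p3 Saturated amplitude, uV (must be <= 0).
#' @param S Sensitivity, m^2.cd^-1.s^-3 (must be > 0).
#' @param td_ms Delay, ms.
#' @return Modeled P3 voltage in uV, same length as `t_ms`.
#' @examples
#' p3_model(1, 13, rm_p3 = -500, S = 1000, td_ms = 3)  # -47.6 uV
#' @export
p3_model <- function(i, t_ms, rm_p3, S, td_ms) {
  if (any(S <= 0)) abort("P3 sensitivity `S` must be positive.")
  if (any(rm_p3 > 0)) abort("`rm_p3` is a corneal-negative amplitude; it must be <= 0.")
  dt_s <- pmax((t_ms - td_ms) / 1000, 0)
  rm_p3 * (1 - exp(-i * S * dt_s^2))
}

## Baseline-correct one waveform: subtract the mean of the pre-stimulus
## (t <= 0) segment. Returns the voltage vector unchanged if no
## pre-stimulus samples exist (with a warning upstream where relevant).
baseline_correct <- function(time_ms, voltage) {
  pre <- time_ms <= 0
  if (!any(pre)) return(voltage)
  voltage - mean(voltage[pre])
}

## Validate a long waveform table (one or more flash energies).
check_waveforms <- function(waves, require_baseline = TRUE) {
  need <- c("energy_log", "time_ms", "voltage_uV")
  miss <- setdiff(need, names(waves))
  if (length(miss) > 0) {
    abort(paste0("Waveform table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(waves$voltage_uV))) abort("Waveform voltages must be finite.")
  if (require_baseline && min(waves$time_ms) > 0) {
    warn("No pre-stimulus samples (t <= 0); baseline correction skipped.")
  }
  invisible(waves)
}

## Sampling interval of a waveform's time grid (ms); errors if not uniform.
sampling_interval <- function(time_ms, tol = 1e-6) {
  dt <- diff(sort(unique(time_ms)))
  if (length(dt) == 0) abort("Waveform needs at least two samples.")
  if (diff(range(dt)) > tol * mean(dt)) abort("Waveform time grid is not uniform.")
  mean(dt)
}
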