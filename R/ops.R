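## Complex frequency response of a digital filter at frequencies f (Hz).
filter_response <- function(b, a, f, fs) {
  vapply(exp(-1i * 2 * pi * f / fs), function(z) {
    sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  }, complex(1))
}

#' Zero-phase band-pass filter for oscillatory-potential extraction
#'
#' Designs a Butterworth band-pass intended for forward-backward
#' (zero-phase) application. Because filtering twice squares the magnitude
#' response, the design pre-widens the single-pass corner frequencies so
#' that the *two-pass* gain is exactly -3 dB at the requested band edges.
#'
#' @param band Pass-band edges in Hz, default `c(50, 180)`.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth prototype order (band-pass order is `2 * order`).
#' @return An object of class `op_filter`: coefficients `b`, `a`, the
#'   widened single-pass corners, `band`, `fs`, `order`.
#' @export
op_bandpass <- function(band = c(50, 180), fs = 4000, order = 2) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must be increasing positive edges (lo < hi).")
  }
  if (band[2] >= fs / 2) abort("Upper band edge must be below the Nyquist frequency.")

  target_db <- 20 * log10(1 / sqrt(2))
  # analog closed-form widening as starting point
  c0 <- (sqrt(2) - 1)^(1 / (2 * order))
  B <- (band[2] - band[1]) / c0
  f1 <- (-B + sqrt(B^2 + 4 * prod(band))) / 2
  f2 <- f1 + B

  gain_db <- function(corners) {
    bt <- signal::butter(order, corners * 2 / fs, type = "pass")
    # filtfilt amplitude gain is |H|^2
    20 * log10(Mod(filter_response(bt$b, bt$a, band, fs))^2)
  }
  obj <- function(p) {
    if (p[1] <= 0 || p[2] >= fs / 2 || p[1] >= p[2]) return(1e6)
    sum((gain_db(p) - target_db)^2)
  }
  if (f2 >= fs / 2) {
    abort("Sampling rate too low to realize -3 dB two-pass corners below Nyquist.")
  }
  fit <- optim(c(f1, f2), obj, control = list(reltol = 1e-14, maxit = 5000))
  corners <- sort(fit$par)
  bt <- signal::butter(order, corners * 2 / fs, type = "pass")
  structure(list(b = bt$b, a = bt$a, corners = corners,
                 band = band, fs = fs, order = order),
            class = "op_filter")
}

#' Two-pass (zero-phase) gain of an OP filter
#'
#' @param filt An [op_bandpass()] object.
#' @param f Frequencies, Hz.
#' @return Gain in dB of the forward-backward application.
#' @export
op_filter_gain_db <- function(filt, f) {
  20 * log10(Mod(filter_response(filt$b, filt$a, f, filt$fs))^2)
}

#' Apply an OP filter forward-backward (zero phase)
#'
#' @param filt An [op_bandpass()] object.
#' @param x Numeric signal sampled at `filt$fs`.
#' @return Filtered signal, same length.
#' @export
op_filtfilt <- function(filt, x) {
  signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), x)
}

#' Extract oscillatory potentials from a P2 trace
#'
#' Band-pass filters the P2 waveform (default 50-180 Hz, -3 dB, zero
#' phase so that implicit times are not shifted) and measures the OPs in
#' the analysis window: `op_amplitude` is the largest trough-to-peak
#' excursion among the wavelets, `op_implicit_ms` the time of the largest
#' peak of the filtered trace.
#'
#' @param p2 Data frame with `time_ms`, `voltage_uV` for one trace
#'   (typically the brightest-flash P2 from [derive_p2()]).
#' @param band Band edges, Hz.
#' @param window_ms OP analysis window, ms.
#' @param filt Optional pre-built [op_bandpass()] (reused across eyes for
#'   speed); must match `band` and the trace's sampling rate.
#' @return An object of class `op_result` with the filtered trace,
#'   `op_amplitude` (uV), `op_implicit_ms` and the band.
#' @export
extract_ops <- function(p2, band = c(50, 180), window_ms = c(10, 60),
                        filt = NULL) {
  dt <- sampling_interval(p2$time_ms)
  fs <- 1000 / dt
  if (fs <= 2 * band[2]) abort("Sampling rate must exceed twice the upper band edge.")
  if (is.null(filt)) {
    filt <- op_bandpass(band, fs)
  } else if (!isTRUE(all.equal(filt$band, band)) ||
             abs(filt$fs - fs) > 1e-6 * fs) {
    abort("Supplied filter does not match the requested band / sampling rate.")
  }
  ord <- order(p2$time_ms)
  t <- p2$time_ms[ord]
  y <- op_filtfilt(filt, p2$voltage_uV[ord])

  inwin <- t >= window_ms[1] & t <= window_ms[2]
  if (!any(inwin)) abort("OP analysis window contains no samples.")
  yw <- y[inwin]; tw <- t[inwin]

  # local extrema by slope sign change; amplitude = largest upstroke
  ds <- sign(diff(yw))
  ext <- which(diff(ds) != 0 & ds[-length(ds)] != 0) + 1
  ext <- sort(unique(c(1, ext, length(yw))))
  upstrokes <- diff(yw[ext])
  op_amplitude <- max(0, upstrokes)
  op_implicit <- tw[which.max(yw)]

  structure(list(
    filtered = tibble(time_ms = t, voltage_uV = y),
    op_amplitude = op_amplitude,
    op_implicit_ms = op_implicit,
    band = band, window_ms = window_ms, corners = filt$corners
  ), class = "op_result")
}

#' @export
print.op_result <- function(x, ...) {
  cat(sprintf("Oscillatory potentials (%g-%g Hz, zero-phase): amplitude %.1f uV, implicit time %.2f ms\n",
              x$band[1], x$band[2], x$op_amplitude, x$op_implicit_ms))
  invisible(x)
}
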