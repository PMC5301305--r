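## Boundary-trace table columns: scan_id, position_um (signed, 0 at the
## optic nerve head center), ilm_um, rnfl_post_um, ipl_um, bm_um (depths,
## increasing posteriorly). BMO endpoint table: scan_id, side, x_um, z_um.

check_boundaries <- function(boundaries) {
  need <- c("scan_id", "position_um", "ilm_um", "rnfl_post_um", "bm_um")
  miss <- setdiff(need, names(boundaries))
  if (length(miss) > 0) {
    abort(paste0("Boundary table missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- boundaries$ilm_um > boundaries$rnfl_post_um |
    boundaries$rnfl_post_um > boundaries$bm_um
  if (any(bad)) abort("Boundary ordering violated: require ILM <= RNFL-posterior <= Bruch's membrane.")
  invisible(boundaries)
}

#' Average layer thickness over the peripapillary analysis window
#'
#' Thickness is the axial depth difference between two boundaries,
#' averaged over all lateral samples 100-800 um (default) on either side
#' of the optic nerve head, pooling both sides of every analyzed B-scan.
#' RNFL thickness is ILM to RNFL-posterior; total retinal thickness (TRT)
#' is ILM to Bruch's membrane.
#'
#' @param boundaries Boundary-trace data frame (see columns above).
#' @param layer `"rnfl"` or `"trt"`.
#' @param window_um Per-side analysis window `c(lo, hi)` in um.
#' @return Mean thickness in um.
#' @export
layer_thickness <- function(boundaries, layer = c("rnfl", "trt"),
                            window_um = c(100, 800)) {
  layer <- match.arg(layer)
  check_boundaries(boundaries)
  if (max(abs(boundaries$position_um)) < window_um[2]) {
    abort("Analysis window extends beyond the lateral extent of the traces.")
  }
  sel <- boundaries |>
    filter(abs(.data$position_um) >= window_um[1],
           abs(.data$position_um) <= window_um[2])
  if (nrow(sel) == 0) abort("Analysis window contains no boundary samples.")
  post <- if (layer == "rnfl") sel$rnfl_post_um else sel$bm_um
  mean(post - sel$ilm_um)
}

#' Bruch's membrane opening width
#'
#' Euclidean distance between the two BMO endpoints of each B-scan,
#' averaged over scans.
#'
#' @param bmo_endpoints Data frame: `scan_id`, `side`, `x_um`, `z_um`
#'   (two endpoints per scan).
#' @return Mean BMO width in um.
#' @export
bmo_width <- function(bmo_endpoints) {
  per_scan <- bmo_endpoints |>
    group_by(.data$scan_id) |>
    group_modify(function(df, key) {
      if (nrow(df) != 2) abort("Each scan needs exactly two BMO endpoints.")
      tibble(width = sqrt(diff(df$x_um)^2 + diff(df$z_um)^2))
    }) |>
    ungroup()
  mean(per_scan$width)
}

#' Minimum rim thickness (MRT)
#'
#' The shortest distance from each Bruch's membrane opening endpoint to
#' the inner limiting membrane, computed as the minimum Euclidean
#' distance over all ILM samples of the same scan; the two endpoint
#' minima are averaged per scan, then over scans.
#'
#' @param boundaries Boundary-trace data frame (provides the ILM).
#' @param bmo_endpoints BMO endpoint data frame.
#' @return Mean MRT in um.
#' @export
minimum_rim_thickness <- function(boundaries, bmo_endpoints) {
  check_boundaries(boundaries)
  per_scan <- bmo_endpoints |>
    group_by(.data$scan_id) |>
    group_modify(function(df, key) {
      ilm <- boundaries |> filter(.data$scan_id == key$scan_id)
      if (nrow(ilm) == 0) abort("No ILM samples for scan; cannot compute MRT.")
      d <- vapply(seq_len(nrow(df)), function(j) {
        min(sqrt((ilm$position_um - df$x_um[j])^2 + (ilm$ilm_um - df$z_um[j])^2))
      }, numeric(1))
      tibble(mrt = mean(d))
    }) |>
    ungroup()
  mean(per_scan$mrt)
}

#' Otsu threshold of a pixel intensity sample
#'
#' Maximizes between-class variance over a 256-bin histogram; used as the
#' default Doppler flow threshold.
#'
#' @param x Numeric vector of pixel values.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x) {
  if (length(x) == 0) abort("Empty pixel sample.")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sig_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sig_b[!is.finite(sig_b)] <- 0
  breaks[which.max(sig_b) + 1]
}

#' Doppler blood-flow surrogate from pixel counts
#'
#' Counts supra-threshold pixels per flow channel (red = arterial flow
#' toward the objective, blue = venous flow away); pixel counts are a
#' surrogate measure of blood flow in arbitrary units.
#'
#' @param scan Data frame of Doppler pixels with `channel`
#'   (`"arterial"` / `"venous"`) and `value` (flow magnitude).
#' @param threshold Numeric threshold, or `"otsu"` (default) to derive it
#'   per channel from the pixel histogram.
#' @return Tibble with `arterial`, `venous`, `total` counts and the
#'   thresholds used.
#' @export
doppler_flow <- function(scan, threshold = "otsu") {
  if (nrow(scan) == 0) abort("Empty Doppler pixel map.")
  count_channel <- function(ch) {
    v <- scan$value[scan$channel == ch]
    if (length(v) == 0) return(c(count = 0, thr = NA_real_))
    thr <- if (identical(threshold, "otsu")) otsu_threshold(v) else threshold
    c(count = sum(v > thr), thr = thr)
  }
  a <- count_channel("arterial"); v <- count_channel("venous")
  tibble(arterial = unname(a["count"]), venous = unname(v["count"]),
         total = unname(a["count"] + v["count"]),
         threshold_arterial = unname(a["thr"]),
         threshold_venous = unname(v["thr"]))
}

#' Pupil diameter
#'
#' Average of the horizontal (180 degree) and vertical (90 degree) pupil
#' widths.
#'
#' @param horizontal_um,vertical_um Pupil widths in um.
#' @return Mean diameter, um.
#' @export
pupil_diameter <- function(horizontal_um, vertical_um) {
  if (any(horizontal_um <= 0) || any(vertical_um <= 0)) {
    abort("Pupil widths must be positive.")
  }
  (horizontal_um + vertical_um) / 2
}

#' Retinal ganglion cell density
#'
#' Density of one counting field: cells per mm^2 from the raw count and
#' the field dimensions (default 290.62 x 290.62 um confocal field).
#'
#' @param count Cell count (>= 0).
#' @param field_w_um,field_h_um Field dimensions, um.
#' @return Density, cells/mm^2.
#' @export
rgc_density <- function(count, field_w_um = 290.62, field_h_um = 290.62) {
  if (any(field_w_um <= 0) || any(field_h_um <= 0)) abort("Field area must be positive.")
  if (any(count < 0)) abort("Counts must be non-negative.")
  count / (field_w_um * field_h_um / 1e6)
}

#' Per-eye morphometry endpoints for a cohort
#'
#' Computes RNFL, TRT, BMO width and MRT from boundary traces, mean RGC
#' density per quadrant (over eccentricities and fields), Doppler flow
#' counts and pupil diameter where the corresponding tables are supplied.
#'
#' @param oct Boundary-trace table with identity columns `animal`, `eye`,
#'   `group` in addition to the per-scan columns.
#' @param bmo BMO endpoint table with the same identity columns.
#' @param rgc Optional RGC count table: identity columns plus `quadrant`,
#'   `eccentricity`, `count`, `field_w_um`, `field_h_um`.
#' @param doppler Optional Doppler pixel table: identity columns plus
#'   `channel`, `value`.
#' @param pupil Optional pupil table: identity columns plus
#'   `horizontal_um`, `vertical_um`.
#' @param window_um Peripapillary analysis window, um.
#' @return Tibble, one row per (animal, eye, group) with available
#'   endpoints (wide; RGC densities as `rgc_<quadrant>`).
#' @export
analyze_morphometry <- function(oct, bmo, rgc = NULL, doppler = NULL,
                                pupil = NULL, window_um = c(100, 800)) {
  ids <- c("animal", "eye", "group")
  out <- oct |>
    group_by(across(all_of(ids))) |>
    group_modify(function(df, key) {
      ep <- semi_join(bmo, key, by = ids)
      tibble(
        rnfl = layer_thickness(df, "rnfl", window_um),
        trt = layer_thickness(df, "trt", window_um),
        bmo = bmo_width(ep),
        mrt = minimum_rim_thickness(df, ep)
      )
    }) |>
    ungroup()
  if (!is.null(rgc)) {
    dens <- rgc |>
      mutate(density = rgc_density(.data$count, .data$field_w_um, .data$field_h_um)) |>
      group_by(across(all_of(c(ids, "quadrant")))) |>
      summarise(density = mean(.data$density), .groups = "drop") |>
      pivot_wider(names_from = "quadrant", values_from = "density",
                  names_prefix = "rgc_")
    out <- left_join(out, dens, by = ids)
  }
  if (!is.null(doppler)) {
    flow <- doppler |>
      group_by(across(all_of(ids))) |>
      group_modify(function(df, key) {
        doppler_flow(df) |> select("arterial", "venous", "total")
      }) |>
      ungroup() |>
      rename(doppler_arterial = "arterial", doppler_venous = "venous",
             doppler_total = "total")
    out <- left_join(out, flow, by = ids)
  }
  if (!is.null(pupil)) {
    ps <- pupil |>
      mutate(pupil_um = pupil_diameter(.data$horizontal_um, .data$vertical_um)) |>
      select(all_of(ids), "pupil_um")
    out <- left_join(out, ps, by = ids)
  }
  out
}
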