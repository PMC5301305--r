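#' Canonical tonometry timepoint labels, in protocol order
#'
#' Five daily baseline readings before surgery, the acute post-surgical
#' block (2 min, 1 h, 3 h), daily readings on post-operative days 1-3,
#' then weekly readings to week 12.
#'
#' @return Character vector of ordered timepoint labels.
#' @export
iop_timepoints <- function() {
  c(paste0("baseline_d", -5:-1), "2min", "1h", "3h",
    paste0("day", 1:3), paste0("week", 1:12))
}

is_baseline_tp <- function(tp) grepl("^baseline", tp)
is_plateau_tp <- function(tp) tp %in% paste0("week", 2:12)

#' Aggregate tonometer readings into one IOP value
#'
#' The instrument protocol takes 10 rebound readings per timepoint and
#' returns their average. Fewer than 10 readings is accepted but flagged
#' as a protocol deviation.
#'
#' @param readings Numeric vector of mmHg readings (10 expected).
#' @return Mean IOP in mmHg.
#' @export
aggregate_readings <- function(readings) {
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0) abort("No tonometer readings supplied.")
  if (length(readings) < 10) {
    warn(sprintf("Protocol deviation: %d tonometer readings (10 expected).",
                 length(readings)))
  }
  mean(readings)
}

#' Baseline IOP of one eye
#'
#' Average of the daily readings over the 5 days before surgery.
#'
#' @param series Data frame for one eye with `timepoint` and `value`
#'   (mmHg, already the 10-reading average).
#' @return Baseline IOP, mmHg.
#' @export
baseline_iop <- function(series) {
  base <- series |> filter(is_baseline_tp(.data$timepoint))
  if (nrow(base) == 0) abort("Series has no baseline timepoints.")
  if (nrow(base) < 5) {
    warn(sprintf("Protocol deviation: %d baseline days (5 expected).", nrow(base)))
  }
  mean(base$value)
}

#' Summarize a treated / control IOP course pair
#'
#' Returns per-eye baseline, post-surgical spike peak, and the chronic
#' plateau mean over weeks 2-12 (IOP is stable from week 2 onwards; week
#' 1 is excluded from the plateau statistic). The between-eye elevation
#' is reported as `delta` (mmHg) and `percent_increase`
#' (100 * (treated/control - 1)), both at full precision and rounded to
#' the nearest integer percent.
#'
#' @param treated,control Data frames with `timepoint`, `value` for the
#'   treated and contralateral control eye of one animal.
#' @return An object of class `iop_summary`: a two-row tibble of per-eye
#'   summaries with attributes `delta`, `percent_increase`,
#'   `percent_increase_rounded`.
#' @export
summarize_course <- function(treated, control) {
  one <- function(series, label) {
    plateau <- series |> filter(is_plateau_tp(.data$timepoint))
    if (nrow(plateau) == 0) abort("Series does not cover the week 2-12 plateau window.")
    post <- series |> filter(!is_baseline_tp(.data$timepoint))
    tibble(
      eye = label,
      baseline_mean = baseline_iop(series),
      spike_peak = max(post$value),
      spike_timepoint = post$timepoint[which.max(post$value)],
      plateau_mean = mean(plateau$value)
    )
  }
  out <- bind_rows(one(treated, "treated"), one(control, "control"))
  delta <- out$plateau_mean[1] - out$plateau_mean[2]
  pct <- percent_change(out$plateau_mean[1], out$plateau_mean[2])
  structure(out, class = c("iop_summary", class(out)),
            delta = delta, percent_increase = pct,
            percent_increase_rounded = round(pct))
}

#' Per-timepoint group means and SEM of an IOP cohort
#'
#' @param cohort Long data frame: `animal`, `eye`, `group`, `timepoint`,
#'   `value` (mmHg).
#' @return Tibble with `group`, `eye`, `timepoint`, `n`, `mean`, `sem`;
#'   cells with n < 2 have `sem = NA` and `flagged = TRUE`.
#' @export
group_iop_table <- function(cohort) {
  out <- cohort |>
    group_by(.data$group, .data$eye, .data$timepoint) |>
    summarise(n = n(), mean = mean(.data$value),
              sem = ifelse(n() >= 2, sd(.data$value) / sqrt(n()), NA_real_),
              .groups = "drop") |>
    mutate(flagged = .data$n < 2,
           timepoint = factor(.data$timepoint, levels = iop_timepoints())) |>
    arrange(.data$group, .data$eye, .data$timepoint)
  if (any(out$flagged)) {
    warn("Some (group, eye, timepoint) cells have n < 2; SEM undefined there.")
  }
  out
}

#' Analyze a cohort tonometry table
#'
#' Averages raw readings where present, summarizes each animal's
#' treated/control pair, and returns per-animal plateau elevations plus
#' the per-timepoint group table.
#'
#' @param iop Long data frame with `animal`, `eye`, `group`, `timepoint`
#'   and either a `value` column or `reading_1` .. `reading_10` columns.
#' @return List with `per_animal` (plateau means, delta, percent),
#'   `group_table` (see [group_iop_table()]).
#' @export
analyze_iop <- function(iop) {
  rd_cols <- grep("^reading_", names(iop), value = TRUE)
  if (!"value" %in% names(iop)) {
    if (length(rd_cols) == 0) abort("IOP table needs `value` or reading_* columns.")
    iop$value <- apply(as.matrix(iop[rd_cols]), 1, aggregate_readings)
  }
  per_animal <- iop |>
    group_by(.data$animal, .data$group) |>
    group_modify(function(df, key) {
      s <- summarize_course(df |> filter(.data$eye == "treated"),
                            df |> filter(.data$eye == "control"))
      tibble(
        baseline_treated = s$baseline_mean[1],
        baseline_control = s$baseline_mean[2],
        spike_peak = s$spike_peak[1],
        plateau_treated = s$plateau_mean[1],
        plateau_control = s$plateau_mean[2],
        delta = attr(s, "delta"),
        percent_increase = attr(s, "percent_increase")
      )
    }) |>
    ungroup()
  list(per_animal = per_animal, group_table = group_iop_table(iop))
}

#' Plot a cohort IOP course (group mean +/- SEM)
#'
#' @param group_table Output of [group_iop_table()].
#' @return A ggplot.
#' @export
plot_iop_course <- function(group_table) {
  dat <- group_table |>
    mutate(series = paste(.data$group, .data$eye, sep = " / "),
           t = as.integer(.data$timepoint))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$mean,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq_along(iop_timepoints()),
                                labels = iop_timepoints(),
                                guide = ggplot2::guide_axis(angle = 60)) +
    ggplot2::labs(x = NULL, y = "IOP (mmHg)",
                  title = "Longitudinal IOP (group mean ± SEM)") +
    ggplot2::theme_minimal()
}
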