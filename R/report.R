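#' Assemble the full study report
#'
#' Computes, for every endpoint, the three study contrasts: treated vs.
#' contralateral control within the OHT group (paired), treated vs.
#' control within the sham group (paired), and C-OHT vs. C-Sham control
#' eyes (unpaired). Animals missing one eye of a pair are dropped from
#' that paired contrast and flagged; endpoints absent from a contrast are
#' flagged as missing. No multiple-testing correction is applied by
#' default (an optional Holm-adjusted column is available as an
#' extension, clearly marked).
#'
#' @param endpoints Long tibble: `animal`, `group` (`"OHT"`/`"sham"`),
#'   `eye` (`"treated"`/`"control"`), `endpoint`, `value`.
#' @param iop Optional output of [analyze_iop()] to embed.
#' @param attrition Optional [attrition_summary()] to embed.
#' @param holm Add a Holm-adjusted p-value column (extension beyond the
#'   uncorrected workflow; default FALSE).
#' @return An object of class `study_report`: `comparisons` tibble (one
#'   row per endpoint x contrast), `flags`, plus any `iop` / `attrition`
#'   components.
#' @export
build_report <- function(endpoints, iop = NULL, attrition = NULL, holm = FALSE) {
  need <- c("animal", "group", "eye", "endpoint", "value")
  if (!all(need %in% names(endpoints))) {
    abort(paste0("Endpoint table needs columns: ", paste(need, collapse = ", ")))
  }
  dup <- endpoints |> count(.data$animal, .data$group, .data$eye, .data$endpoint) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate endpoint keys, e.g. animal %s endpoint %s.",
                  dup$animal[1], dup$endpoint[1]))
  }
  flags <- list()
  note <- function(msg) flags[[length(flags) + 1]] <<- msg

  paired_contrast <- function(grp, label) {
    endpoints |>
      filter(.data$group == grp) |>
      group_by(.data$endpoint) |>
      group_modify(function(df, key) {
        wide <- df |> select("animal", "eye", "value") |>
          pivot_wider(names_from = "eye", values_from = "value")
        if (!all(c("treated", "control") %in% names(wide))) {
          note(sprintf("Endpoint '%s' missing an eye in contrast %s.",
                       key$endpoint, label))
          return(tibble())
        }
        ok <- !is.na(wide$treated) & !is.na(wide$control)
        if (sum(!ok) > 0) {
          note(sprintf("Endpoint '%s': %d animal(s) dropped from %s (incomplete pair).",
                       key$endpoint, sum(!ok), label))
        }
        if (sum(ok) < 2) {
          note(sprintf("Endpoint '%s': fewer than 2 complete pairs in %s.",
                       key$endpoint, label))
          return(tibble())
        }
        paired_comparison(wide$treated[ok], wide$control[ok]) |>
          select(-"endpoint")
      }) |>
      ungroup() |>
      mutate(contrast = label, .after = "endpoint")
  }

  control_contrast <- function() {
    endpoints |>
      filter(.data$eye == "control") |>
      group_by(.data$endpoint) |>
      group_modify(function(df, key) {
        a <- df$value[df$group == "OHT"]; b <- df$value[df$group == "sham"]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2) {
          note(sprintf("Endpoint '%s': insufficient control eyes for C-OHT vs C-Sham.",
                       key$endpoint))
          return(tibble())
        }
        unpaired_comparison(a, b) |> select(-"endpoint")
      }) |>
      ungroup() |>
      mutate(contrast = "C-OHT_vs_C-Sham", .after = "endpoint")
  }

  comparisons <- bind_rows(
    paired_contrast("OHT", "OHT_treated_vs_control"),
    paired_contrast("sham", "sham_treated_vs_control"),
    control_contrast()
  )
  if (holm && nrow(comparisons) > 0) {
    comparisons <- comparisons |>
      group_by(.data$contrast) |>
      mutate(p_holm_extension = stats::p.adjust(.data$p_value, "holm")) |>
      ungroup()
  }
  structure(list(comparisons = comparisons, flags = unlist(flags),
                 iop = iop, attrition = attrition,
                 multiple_testing = if (holm) "holm column (extension)" else "none"),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", nrow(x$comparisons), "endpoint x contrast comparisons\n")
  cat("Multiple-testing correction:", x$multiple_testing, "\n")
  if (!is.null(x$attrition)) {
    cat(sprintf("Attrition: %d/%d surgeries retained (%.0f%%)\n",
                attr(x$attrition, "successes"), attr(x$attrition, "attempted"),
                attr(x$attrition, "success_percent")))
  }
  sig <- x$comparisons |> filter(.data$p_value < 0.05)
  if (nrow(sig) > 0) {
    cat("Significant at alpha = 0.05 (uncorrected):\n")
    print(as.data.frame(sig |>
                          select("endpoint", "contrast", "statistic", "df",
                                 "p_value", "pct_ratio_of_means")),
          row.names = FALSE, digits = 3)
  }
  if (length(x$flags) > 0) {
    cat("Flags:\n"); for (f in x$flags) cat(" -", f, "\n")
  }
  invisible(x)
}

#' @rdname build_report
#' @param x A `study_report`.
#' @param ... Unused.
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) x$comparisons

#' @rdname build_report
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble(n_comparisons = nrow(x$comparisons),
         n_significant = sum(x$comparisons$p_value < 0.05),
         n_flags = length(x$flags),
         multiple_testing = x$multiple_testing)
}

#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  dat <- object$comparisons |>
    mutate(sig = .data$p_value < 0.05)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pct_ratio_of_means,
                                    y = .data$endpoint,
                                    colour = .data$sig)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Treated vs control change (%)", y = NULL,
                  colour = "p < 0.05",
                  title = "Per-endpoint treated vs control effects") +
    ggplot2::theme_minimal()
}
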