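#' Percent change of a treated value relative to its control
#'
#' `100 * (treated - control) / control`; presentation rounds to the
#' nearest integer percent, full precision is always returned.
#'
#' @param treated,control Numeric values (control must be non-zero).
#' @return Percent change (full precision; round for presentation).
#' @export
percent_change <- function(treated, control) {
  if (any(control == 0)) abort("Control value must be non-zero for percent change.")
  100 * (treated - control) / control
}

comparison_row <- function(endpoint, test, statistic, df, p, n,
                           mean_a, sem_a, mean_b, sem_b,
                           pct_mean_of_ratios = NA_real_,
                           pct_ratio_of_means = NA_real_) {
  tibble(endpoint = endpoint, test = test, statistic = statistic,
         df = df, p_value = p, n = n,
         mean_treated = mean_a, sem_treated = sem_a,
         mean_control = mean_b, sem_control = sem_b,
         pct_mean_of_ratios = pct_mean_of_ratios,
         pct_ratio_of_means = pct_ratio_of_means)
}

sem <- function(x) sd(x) / sqrt(length(x))

#' Paired comparison of treated vs. contralateral control eyes
#'
#' Two-sided paired t-test, pairing by animal. Percent change is reported
#' both as the mean of per-animal treated/control ratios and as the ratio
#' of group means.
#'
#' @param treated,control Numeric vectors of equal length, ordered by
#'   animal.
#' @param endpoint Endpoint label for the result row.
#' @return One-row comparison tibble.
#' @export
paired_comparison <- function(treated, control, endpoint = "") {
  if (length(treated) != length(control)) abort("Paired vectors must have equal length.")
  if (length(treated) < 2) abort("Paired comparison needs at least 2 pairs.")
  d <- treated - control
  if (sd(d) == 0) {
    # constant differences: zero (p = 1) or a deterministic shift (p -> 0)
    tt <- list(statistic = c(t = if (all(d == 0)) 0 else sign(d[1]) * Inf),
               parameter = c(df = length(d) - 1),
               p.value = if (all(d == 0)) 1 else 0)
  } else {
    tt <- t.test(treated, control, paired = TRUE)
  }
  comparison_row(endpoint, "paired-t",
                 unname(tt$statistic), unname(tt$parameter), tt$p.value,
                 length(treated),
                 mean(treated), sem(treated), mean(control), sem(control),
                 pct_mean_of_ratios = mean(percent_change(treated, control)),
                 pct_ratio_of_means = percent_change(mean(treated), mean(control)))
}

#' Unpaired comparison of two groups
#'
#' Two-sided two-sample t-test; the equal-variance (pooled) form is the
#' default, matching a workflow in which homogeneity of variance is
#' screened beforehand; set `var_equal = FALSE` for the Welch form when
#' screening fails.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param endpoint Endpoint label.
#' @param var_equal Use the pooled-variance statistic (default TRUE).
#' @return One-row comparison tibble.
#' @export
unpaired_comparison <- function(a, b, endpoint = "", var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("Each group needs at least 2 observations.")
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate constant samples: no within-group variance
    tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else
                               sign(mean(a) - mean(b)) * Inf),
               parameter = c(df = length(a) + length(b) - 2),
               p.value = if (mean(a) == mean(b)) 1 else 0)
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
  }
  comparison_row(endpoint, "unpaired-t",
                 unname(tt$statistic), unname(tt$parameter), tt$p.value,
                 length(a) + length(b),
                 mean(a), sem(a), mean(b), sem(b),
                 pct_ratio_of_means = percent_change(mean(a), mean(b)))
}

#' Two-way repeated-measures ANOVA (split-plot)
#'
#' Between-subject factor `group`, within-subject factor `time`, subject
#' as the repeated factor. Implemented directly from the sums-of-squares
#' decomposition of the complete balanced split-plot design:
#' between-subject variation splits into group and subject-within-group;
#' within-subject variation splits into time, group x time, and the
#' residual. F for group uses subject-within-group as its error term; F
#' for time and the interaction use the within-subject residual. No
#' sphericity correction is applied (noted in the output).
#'
#' @param data Data frame with columns `subject`, `group`, `time`,
#'   `value`; every subject must be observed at every timepoint.
#' @param endpoint Endpoint label.
#' @return An object of class `rm_anova`: ANOVA table tibble (`term`,
#'   `ss`, `df`, `ms`, `f`, `p_value`) plus bookkeeping.
#' @export
rm_anova_two_way <- function(data, endpoint = "") {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(data))) abort("Need columns subject, group, time, value.")
  tab <- table(data$subject, data$time)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    abort(sprintf("Design not complete/balanced: subject %s at time %s observed %d time(s).",
                  rownames(tab)[bad[1, 1]], colnames(tab)[bad[1, 2]],
                  tab[bad[1, , drop = FALSE]]))
  }
  grp_of <- data |> distinct(.data$subject, .data$group)
  if (any(duplicated(grp_of$subject))) abort("A subject appears in more than one group.")

  y <- data$value
  grand <- mean(y)
  n_time <- length(unique(data$time))
  n_subj <- length(unique(data$subject))
  a <- length(unique(data$group))

  subj_means <- data |> group_by(.data$subject, .data$group) |>
    summarise(m = mean(.data$value), .groups = "drop")
  grp_means <- data |> group_by(.data$group) |>
    summarise(m = mean(.data$value), n_subj = n_distinct(.data$subject),
              .groups = "drop")
  time_means <- data |> group_by(.data$time) |>
    summarise(m = mean(.data$value), .groups = "drop")
  cell_means <- data |> group_by(.data$group, .data$time) |>
    summarise(m = mean(.data$value), n = n(), .groups = "drop") |>
    left_join(grp_means |> select("group", gm = "m"), by = "group") |>
    left_join(time_means |> select("time", tm = "m"), by = "time")

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- n_time * sum((subj_means$m - grand)^2)
  ss_group <- n_time * sum(grp_means$n_subj * (grp_means$m - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  ss_time <- n_subj * sum((time_means$m - grand)^2)
  ss_int <- sum(cell_means$n * (cell_means$m - cell_means$gm - cell_means$tm + grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_time - ss_int

  df_group <- a - 1
  df_subj <- n_subj - a
  df_time <- n_time - 1
  df_int <- (a - 1) * (n_time - 1)
  df_err <- (n_subj - a) * (n_time - 1)

  ms <- c(ss_group / df_group, ss_subj / df_subj, ss_time / df_time,
          ss_int / df_int, ss_err / df_err)
  f_group <- ms[1] / ms[2]
  f_time <- ms[3] / ms[5]
  f_int <- ms[4] / ms[5]
  tbl <- tibble(
    term = c("group", "subject_within_group", "time", "group_time", "residual"),
    ss = c(ss_group, ss_subj, ss_time, ss_int, ss_err),
    df = c(df_group, df_subj, df_time, df_int, df_err),
    ms = ms,
    f = c(f_group, NA, f_time, f_int, NA),
    p_value = c(pf(f_group, df_group, df_subj, lower.tail = FALSE), NA,
                pf(f_time, df_time, df_err, lower.tail = FALSE),
                pf(f_int, df_int, df_err, lower.tail = FALSE), NA)
  )
  structure(list(table = tbl, endpoint = endpoint,
                 n_subjects = n_subj, n_times = n_time, n_groups = a,
                 sphericity_correction = "none"),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA%s (%d subjects x %d times, %d groups; sphericity correction: %s)\n",
              if (nzchar(x$endpoint)) paste0(" [", x$endpoint, "]") else "",
              x$n_subjects, x$n_times, x$n_groups, x$sphericity_correction))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @rdname rm_anova_two_way
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname rm_anova_two_way
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_times = x$n_times,
         n_groups = x$n_groups,
         p_group = x$table$p_value[x$table$term == "group"],
         p_time = x$table$p_value[x$table$term == "time"],
         p_interaction = x$table$p_value[x$table$term == "group_time"])
}

#' Screen test assumptions: normality and homogeneity of variance
#'
#' Shapiro-Wilk normality per sample (needs n >= 3) and Bartlett's test
#' of equal variances across samples. Downstream tests should annotate
#' their results when screening fails.
#'
#' @param samples Named list of numeric vectors.
#' @param alpha Screening level.
#' @return List with `normality` tibble (per sample W and p), `variance`
#'   tibble (Bartlett K^2, df, p) and a logical `pass`.
#' @export
assumption_screen <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 1) abort("Supply a list of samples.")
  if (any(vapply(samples, length, 1L) < 3)) {
    abort("Normality screening needs n >= 3 in every sample.")
  }
  nm <- names(samples) %||% paste0("sample", seq_along(samples))
  normality <- purrr::map2(samples, nm, function(x, n) {
    sw <- shapiro.test(x)
    tibble(sample = n, n = length(x), w = unname(sw$statistic),
           p_value = sw$p.value)
  }) |> list_rbind()
  variance <- if (length(samples) >= 2) {
    bt <- bartlett.test(samples)
    tibble(statistic = unname(bt$statistic), df = unname(bt$parameter),
           p_value = bt$p.value)
  } else {
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  list(normality = normality, variance = variance,
       pass = all(normality$p_value > alpha) &&
         (is.na(variance$p_value[1]) || variance$p_value[1] > alpha))
}

#' Surgical attrition accounting
#'
#' Success percentage over attempted surgeries and per-cause complication
#' shares over failures, with nearest-integer presentation.
#'
#' @param attempted Number of attempted surgeries.
#' @param successes Number retained at the success checkpoint.
#' @param causes Named integer vector of complication counts; must sum to
#'   `attempted - successes`.
#' @return An object of class `attrition_summary` (a tibble of causes
#'   with shares, plus attributes `attempted`, `successes`,
#'   `success_percent`).
#' @export
attrition_summary <- function(attempted, successes, causes = c()) {
  failures <- attempted - successes
  if (length(causes) > 0 && sum(causes) != failures) {
    abort(sprintf("Inconsistent totals: %d successes + %d complications != %d attempted.",
                  successes, sum(causes), attempted))
  }
  tbl <- if (length(causes) > 0) {
    tibble(cause = names(causes), n = as.integer(causes),
           share_of_failures = 100 * as.integer(causes) / failures) |>
      mutate(share_rounded = round(.data$share_of_failures))
  } else {
    tibble(cause = character(), n = integer(),
           share_of_failures = numeric(), share_rounded = numeric())
  }
  structure(tbl, class = c("attrition_summary", class(tbl)),
            attempted = attempted, successes = successes,
            success_percent = 100 * successes / attempted)
}
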