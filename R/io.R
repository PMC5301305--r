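## File-format contract: comma-separated, dot-decimal, UTF-8, header row,
## preceded by '#' comment lines carrying package version, config hash
## and seed so every output is traceable to its run.

study_table_names <- c("waveforms", "iop", "oct", "bmo", "doppler",
                       "rgc", "pupil", "qpcr", "ground_truth")

#' Write a simulated study to delimited-text tables
#'
#' One CSV per table. Each file starts with comment lines (`#`) recording
#' the package version, a hash of the generating configuration, and the
#' seed.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_tables <- function(study, dir) {
  if (!inherits(study, "simulated_study")) abort("`study` must be a simulated_study.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(study$config)
  header <- c(
    paste0("# ohtcohort ", as.character(utils::packageVersion("ohtcohort"))),
    paste0("# config_hash ", hash),
    paste0("# seed ", study$seed))
  paths <- vapply(study_table_names, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    tbl <- study[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0) return(NA_character_)
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(header, con)
    close(con)
    readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
    path
  }, character(1))
  att <- study$attrition
  readr::write_csv(
    tibble(cause = c("success", att$cause),
           n = c(attr(att, "successes"), att$n)),
    file.path(dir, "attrition.csv"))
  invisible(paths[!is.na(paths)])
}

#' Read study tables back from a directory
#'
#' @param dir Directory produced by [write_study_tables()].
#' @return Named list of tibbles (missing tables are `NULL`).
#' @export
read_study_tables <- function(dir) {
  out <- lapply(setNames(study_table_names, study_table_names), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) return(NULL)
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  })
  att_path <- file.path(dir, "attrition.csv")
  if (file.exists(att_path)) {
    att <- readr::read_csv(att_path, show_col_types = FALSE, progress = FALSE)
    succ <- att$n[att$cause == "success"]
    causes <- att |> filter(.data$cause != "success")
    out$attrition <- attrition_summary(succ + sum(causes$n), succ,
                                       setNames(causes$n, causes$cause))
  }
  out
}

#' Run the full analysis chain on a simulated or loaded study
#'
#' Executes ERG decomposition, IOP summarization, morphometry, qPCR
#' quantification and the cohort statistics end-to-end, and assembles the
#' study report. The per-eye endpoint table combines: ERG parameters
#' (|RmP3|, log S, Vmax, P2 log sensitivity, OP amplitude/implicit time,
#' pSTR amplitude/implicit time), plateau IOP, OCT metrics, Doppler
#' counts, per-quadrant RGC densities, and normalized gene expression.
#'
#' @param study A `simulated_study` or the list returned by
#'   [read_study_tables()].
#' @param ... Passed to [erg_decompose()].
#' @return List of class `study_analysis`: `erg`, `iop`, `morphometry`,
#'   `qpcr`, `endpoints` (long per-eye table), `report`
#'   (a [build_report()] result).
#' @export
analyze_study <- function(study, ...) {
  for (nm in c("waveforms", "iop", "oct", "bmo")) {
    if (is.null(study[[nm]]) || nrow(study[[nm]]) == 0) {
      abort(paste0("Required input table missing or empty: ", nm))
    }
  }
  erg <- erg_decompose(study$waveforms, ...)
  iop <- analyze_iop(study$iop)
  morph <- analyze_morphometry(study$oct, study$bmo, rgc = study$rgc,
                               doppler = study$doppler, pupil = study$pupil)
  qp <- if (!is.null(study$qpcr) && nrow(study$qpcr) > 0) analyze_qpcr(study$qpcr)

  ids <- c("animal", "eye", "group")
  wide <- erg |>
    mutate(p3_amplitude = abs(.data$rm_p3)) |>
    select(all_of(ids), "p3_amplitude", "log_S", "vmax",
           "p2_log_sensitivity", "op_amplitude", "op_implicit_ms",
           "pstr_amplitude", "pstr_implicit_ms") |>
    left_join(morph, by = ids)
  plateau <- study$iop |> (\(d) {
    rd <- grep("^reading_", names(d), value = TRUE)
    if (!"value" %in% names(d)) {
      d$value <- rowMeans(as.matrix(d[rd]))
    }
    d |> filter(is_plateau_tp(.data$timepoint)) |>
      group_by(across(all_of(ids))) |>
      summarise(iop_plateau = mean(.data$value), .groups = "drop")
  })()
  wide <- left_join(wide, plateau, by = ids)
  if (!is.null(qp)) {
    expr_wide <- qp$expression |>
      select(all_of(ids), "gene", "normalized") |>
      pivot_wider(names_from = "gene", values_from = "normalized",
                  names_prefix = "expr_") |>
      left_join(qp$ratios |> select(all_of(ids), "p2x7_adora3"), by = ids)
    wide <- left_join(wide, expr_wide, by = ids)
  }
  endpoints <- wide |>
    pivot_longer(-all_of(ids), names_to = "endpoint", values_to = "value") |>
    filter(!is.na(.data$value))
  report <- build_report(endpoints, iop = iop, attrition = study$attrition)
  structure(list(erg = erg, iop = iop, morphometry = morph, qpcr = qp,
                 endpoints = endpoints, report = report),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis of", n_distinct(x$endpoints$animal), "animals\n")
  print(x$report)
  invisible(x)
}
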