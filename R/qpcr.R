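## Assay panel (gene symbols); runs are keyed by these names.
qpcr_panel <- c("P2x7", "Adora3", "Panx1", "Trpv4", "Entpd1", "Hprt")

#' Fit a qPCR external standard curve
#'
#' Least-squares line `Ct = intercept + slope * log10(copies)` through
#' the standard dilution points (four-point curves are run on every run).
#' Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (a slope of -3.322 cycles/decade is 100%).
#'
#' @param points Data frame with `copies` (nominal copy number) and `ct`.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`, `flagged` (TRUE when the
#'   slope is non-negative or efficiency falls outside 60-130%).
#' @export
fit_standard_curve <- function(points) {
  if (!all(c("copies", "ct") %in% names(points))) {
    abort("`points` needs columns copies, ct.")
  }
  if (nrow(points) < 2) abort("Standard curve needs at least 2 points.")
  if (length(unique(points$copies)) < 2) {
    abort("Standard curve points must have distinct copy numbers.")
  }
  fit <- lm(ct ~ log10(copies), data = points)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  flagged <- FALSE
  if (slope >= 0) {
    warn("Standard curve slope is non-negative; curve flagged invalid.")
    flagged <- TRUE
    efficiency <- NA_real_
  } else {
    efficiency <- 10^(-1 / slope) - 1
    if (efficiency < 0.6 || efficiency > 1.3) {
      warn(sprintf("Amplification efficiency %.0f%% outside 60-130%%; curve flagged.",
                   100 * efficiency))
      flagged <- TRUE
    }
  }
  r2 <- if (nrow(points) > 2 || TRUE) {
    ss_res <- sum(resid(fit)^2)
    ss_tot <- sum((points$ct - mean(points$ct))^2)
    if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  }
  structure(list(slope = slope, intercept = intercept,
                 efficiency = efficiency, r_squared = r2,
                 n_points = nrow(points), flagged = flagged,
                 points = as_tibble(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.2f %+.3f log10(copies); efficiency %.1f%%, r^2 = %.4f (%d points)%s\n",
              x$intercept, x$slope, 100 * x$efficiency, x$r_squared,
              x$n_points, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the standard line: `copies = 10^((intercept - ct) / (-slope))`.
#' Triplicate Cts should be quantified individually and averaged on the
#' linear copy scale (see [analyze_qpcr()]).
#'
#' @param ct Threshold cycle(s).
#' @param curve A [fit_standard_curve()] object.
#' @return Copy number(s).
#' @export
quantify <- function(ct, curve) {
  if (!inherits(curve, "standard_curve")) abort("`curve` must be a standard_curve.")
  if (curve$flagged && curve$slope >= 0) abort("Cannot quantify against an invalid (non-negative slope) curve.")
  if (any(!is.finite(ct))) abort("Non-finite Ct value.")
  10^((curve$intercept - ct) / (-curve$slope))
}

#' Housekeeping normalization
#'
#' Expresses a gene's absolute copy number relative to the housekeeping
#' gene Hprt measured in the same sample.
#'
#' @param gene_copies,hprt_copies Absolute copy numbers.
#' @return Dimensionless expression ratio.
#' @export
normalize_expression <- function(gene_copies, hprt_copies) {
  if (any(hprt_copies <= 0)) abort("Hprt copies must be positive.")
  gene_copies / hprt_copies
}

#' Purinergic receptor balance ratio
#'
#' Ratio of P2x7 to Adora3 normalized expression, an index of purinergic
#' signaling tone.
#'
#' @param p2x7,adora3 Normalized expression values.
#' @return Ratio.
#' @export
receptor_ratio <- function(p2x7, adora3) {
  if (any(adora3 <= 0)) abort("Adora3 expression must be positive.")
  p2x7 / adora3
}

#' Quantify a cohort qPCR table
#'
#' Per run and gene, fits the standard curve from that run's standard
#' dilutions (curves are never pooled across runs), quantifies each
#' sample's triplicate Cts, averages them on the linear copy scale,
#' normalizes to the sample's Hprt copies, and computes the P2x7/Adora3
#' ratio. Negative-control wells with Ct below the no-amplification
#' threshold flag the run.
#'
#' @param qpcr Long data frame: `run_id`, `gene`, `role`
#'   (`"standard"` / `"sample"` / `"ntc"`), `animal`, `eye`, `group`
#'   (samples only), `nominal_copies` (standards only), `ct`.
#' @param ntc_ct_threshold Ct below which a negative control counts as
#'   amplification (default 40).
#' @return List with `expression` (one row per sample x gene:
#'   `copies`, `cv`, `normalized`), `ratios` (P2x7/Adora3 per sample),
#'   `curves` (per run x gene curve parameters).
#' @export
analyze_qpcr <- function(qpcr, ntc_ct_threshold = 40) {
  if (!all(c("run_id", "gene", "role", "ct") %in% names(qpcr))) {
    abort("qPCR table needs columns run_id, gene, role, ct.")
  }
  unknown <- setdiff(unique(qpcr$gene), qpcr_panel)
  if (length(unknown) > 0) {
    abort(paste0("Genes outside the assay panel: ", paste(unknown, collapse = ", ")))
  }
  ntc <- qpcr |> filter(.data$role == "ntc", .data$ct < ntc_ct_threshold)
  if (nrow(ntc) > 0) {
    warn(sprintf("Negative-control amplification in run(s): %s",
                 paste(unique(ntc$run_id), collapse = ", ")))
  }
  curves <- qpcr |>
    filter(.data$role == "standard") |>
    group_by(.data$run_id, .data$gene) |>
    group_modify(function(df, key) {
      cv <- fit_standard_curve(df |> transmute(copies = .data$nominal_copies,
                                               ct = .data$ct))
      tibble(curve = list(cv), slope = cv$slope, intercept = cv$intercept,
             efficiency = cv$efficiency, r_squared = cv$r_squared,
             flagged = cv$flagged)
    }) |>
    ungroup()

  expression <- qpcr |>
    filter(.data$role == "sample") |>
    group_by(.data$run_id, .data$gene, .data$animal, .data$eye, .data$group) |>
    group_modify(function(df, key) {
      cv <- curves |>
        filter(.data$run_id == key$run_id, .data$gene == key$gene)
      if (nrow(cv) == 0) abort(sprintf("No standard curve for run %s gene %s.",
                                       key$run_id, key$gene))
      copies <- quantify(df$ct, cv$curve[[1]])
      tibble(copies = mean(copies),
             cv = if (length(copies) > 1) sd(copies) / mean(copies) else NA_real_,
             n_wells = length(copies))
    }) |>
    ungroup()

  hprt <- expression |>
    filter(.data$gene == "Hprt") |>
    select("animal", "eye", "group", hprt_copies = "copies")
  expression <- expression |>
    filter(.data$gene != "Hprt") |>
    left_join(hprt, by = c("animal", "eye", "group")) |>
    mutate(normalized = normalize_expression(.data$copies, .data$hprt_copies))

  ratios <- expression |>
    filter(.data$gene %in% c("P2x7", "Adora3")) |>
    select("animal", "eye", "group", "gene", "normalized") |>
    pivot_wider(names_from = "gene", values_from = "normalized") |>
    mutate(p2x7_adora3 = receptor_ratio(.data$P2x7, .data$Adora3))

  list(expression = expression, ratios = ratios,
       curves = curves |> select(-"curve"))
}
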