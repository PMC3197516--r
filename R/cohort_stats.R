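#' Median and interquartile summary of a metric
#'
#' Summarizes a cohort metric as median and 25th/75th percentiles. The
#' default quantile convention is the weighted average at position
#' `(n+1)p` (`stats::quantile` type 6), the convention SPSS uses for
#' EXAMINE-style summaries; alternatives are available for
#' cross-checking.
#'
#' @param values Nonempty numeric vector of finite values.
#' @param metric_name Label for the summarized metric.
#' @param quantile_method One of `"spss"` (type 6, default), `"linear"`
#'   (type 7, the R default) or `"averaged_inverted_cdf"` (type 2).
#' @return An object of class `cohort_summary`: list with `metric_name`,
#'   `n`, `median`, `q25`, `q75`.
#' @examples
#' summarize_metric(c(1, 2, 3, 4), "demo")  # q25 1.25, median 2.5, q75 3.75
#' @export
summarize_metric <- function(values, metric_name = "metric",
                             quantile_method = c("spss", "linear",
                                                 "averaged_inverted_cdf")) {
  quantile_method <- match.arg(quantile_method)
  values <- as.numeric(values)
  if (!length(values)) stop("cannot summarize an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  type <- switch(quantile_method, spss = 6, linear = 7,
                 averaged_inverted_cdf = 2)
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = type))
  structure(list(metric_name = metric_name, n = length(values),
                 median = q[2], q25 = q[1], q75 = q[3]),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(x$metric_name, ": n = ", x$n, ", median ",
      format(x$median, digits = 4), " (", format(x$q25, digits = 4),
      "-", format(x$q75, digits = 4), ")\n", sep = "")
  invisible(x)
}

# pull one phase-level metric column out of a scenario_metrics list
.phase_values <- function(cohort, metric_name, phase) {
  vapply(cohort, function(m) {
    i <- which(m$phases$phase == phase)
    if (!length(i)) return(NA_real_)
    m$phases[[metric_name]][i]
  }, numeric(1))
}

#' Compare a metric between first responders and the arrest team
#'
#' Extracts the per-scenario first-responder-phase and team-phase values
#' of a metric (e.g. `"nfr"` or `"nfr_adj"`), summarizes both groups as
#' median and interquartile range, and tests the group difference with
#' the unpaired two-sided Mann-Whitney U test ([mann_whitney_exact()]).
#' The unpaired analysis is the primary one; a paired Wilcoxon
#' signed-rank variant (the phases are paired within scenario) is
#' available as a clearly labelled extension.
#'
#' @param cohort List of [scenario_metrics()] objects, each with both
#'   phases.
#' @param metric_name Column of the phase table to compare (default
#'   `"nfr"`).
#' @param quantile_method Passed to [summarize_metric()].
#' @param paired If `TRUE`, additionally run the paired Wilcoxon
#'   signed-rank test (off by default).
#' @param alpha Significance threshold reported alongside the p-value
#'   (default 0.05).
#' @return An object of class `phase_comparison`: list with
#'   `first_responders` and `team` ([summarize_metric()] results),
#'   `test` (an `mw_test`), `significant` (logical vs `alpha`), and
#'   optionally `paired_test`.
#' @export
compare_phases <- function(cohort, metric_name = "nfr",
                           quantile_method = "spss", paired = FALSE,
                           alpha = 0.05) {
  fr <- .phase_values(cohort, metric_name, "first_responders")
  tm <- .phase_values(cohort, metric_name, "team")
  missing <- vapply(cohort, function(m)
    !all(c("first_responders", "team") %in% m$phases$phase), logical(1))
  if (any(missing)) {
    ids <- vapply(cohort[missing], `[[`, character(1), "scenario_id")
    stop("scenario(s) missing a phase: ", paste(ids, collapse = ", "))
  }
  test <- mann_whitney_exact(fr, tm)
  out <- list(
    metric_name = metric_name,
    first_responders = summarize_metric(fr, paste0(metric_name,
                                                   " (first responders)"),
                                        quantile_method),
    team = summarize_metric(tm, paste0(metric_name, " (team)"),
                            quantile_method),
    test = test,
    alpha = alpha,
    significant = test$p_two_sided < alpha
  )
  if (paired)
    out$paired_test <- wilcox.test(fr, tm, paired = TRUE, exact = FALSE)
  structure(out, class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat("Phase comparison of ", x$metric_name, " (n = ",
      x$first_responders$n, " scenarios)\n", sep = "")
  print(x$first_responders)
  print(x$team)
  print(x$test)
  cat(if (x$significant) "significant" else "not significant",
      " at alpha = ", x$alpha, "\n", sep = "")
  if (!is.null(x$paired_test))
    cat("paired Wilcoxon signed-rank (extension): p = ",
        format.pval(x$paired_test$p.value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Cohort summary table of resuscitation quality markers
#'
#' One row per quality marker of the overall simulation (compression
#' rate, delivered compressions per minute, time to CPR, defibrillator
#' arrival, first rhythm, NFR and adjusted NFR), each summarized as
#' median and interquartile range across scenarios. Fractions are also
#' rendered as whole percentages.
#'
#' @param cohort List of [scenario_metrics()] objects.
#' @param quantile_method Passed to [summarize_metric()].
#' @return Data frame with columns `metric`, `n`, `median`, `q25`,
#'   `q75`, `display` (percentages to 0 decimals for ratio rows).
#' @export
cohort_table <- function(cohort, quantile_method = "spss") {
  ov <- function(col) .phase_values(cohort, col, "overall")
  mk <- function(nm) vapply(cohort, function(m) m$markers[[nm]],
                            numeric(1))
  specs <- list(
    list("Compression rate (comp/min)", ov("rate_cpm"), FALSE),
    list("Compressions (actual comp. given/min)", ov("delivered_cpm"),
         FALSE),
    list("Time to initiating of CPR (sec)", mk("time_to_cpr_s"), FALSE),
    list("Time to arrival of defibrillator in room (sec)",
         mk("time_to_defib_arrival_s"), FALSE),
    list("Time to first rhythm on defibrillator (sec)",
         mk("time_to_first_rhythm_s"), FALSE),
    list("NFR (%)", ov("nfr"), TRUE),
    list("NFR_adj (%)", ov("nfr_adj"), TRUE)
  )
  rows <- lapply(specs, function(sp) {
    v <- sp[[2]]
    v <- v[is.finite(v)]
    if (!length(v))
      return(data.frame(metric = sp[[1]], n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, display = ""))
    if (sp[[3]]) v <- 100 * v
    s <- summarize_metric(v, sp[[1]], quantile_method)
    disp <- if (sp[[3]])
      sprintf("%.0f (%.0f-%.0f)", s$median, s$q25, s$q75)
    else sprintf("%.0f (%.0f-%.0f)", s$median, s$q25, s$q75)
    data.frame(metric = sp[[1]], n = s$n, median = s$median,
               q25 = s$q25, q75 = s$q75, display = disp)
  })
  do.call(rbind, rows)
}

#' Phase comparison table for NFR and adjusted NFR
#'
#' Mirrors the first-responders-versus-team layout: for each of NFR and
#' NFR adjusted, the group medians and quartiles (as whole percentages)
#' plus the two-sided Mann-Whitney p-value.
#'
#' @inheritParams cohort_table
#' @return Data frame with one row per metric.
#' @export
comparison_table <- function(cohort, quantile_method = "spss") {
  rows <- lapply(c(nfr = "nfr", nfr_adj = "nfr_adj"), function(mn) {
    cmp <- compare_phases(cohort, mn, quantile_method)
    data.frame(
      metric = paste0(toupper(sub("_adj", "", mn)),
                      if (grepl("adj", mn)) "_adj (%)" else " (%)"),
      fr_median = 100 * cmp$first_responders$median,
      fr_q25 = 100 * cmp$first_responders$q25,
      fr_q75 = 100 * cmp$first_responders$q75,
      team_median = 100 * cmp$team$median,
      team_q25 = 100 * cmp$team$q25,
      team_q75 = 100 * cmp$team$q75,
      u_statistic = cmp$test$u_statistic,
      p_value = cmp$test$p_two_sided,
      method = cmp$test$method
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
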