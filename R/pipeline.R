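#' Analyze a cohort of event logs
#'
#' Runs [scenario_metrics()] over every log and assembles the
#' per-scenario table, the cohort quality-marker summary and the
#' first-responders-versus-team comparison.
#'
#' @param logs List of [event_log()] objects.
#' @param policy An [allowance_policy()].
#' @param quantile_method Passed to the summaries.
#' @return List with `metrics` (list of `scenario_metrics`),
#'   `per_scenario` (data frame, one row per scenario), `cohort`
#'   ([cohort_table()]) and `comparison` ([comparison_table()], `NULL`
#'   when some scenario lacks a handover).
#' @export
analyze_cohort <- function(logs, policy = allowance_policy(),
                           quantile_method = "spss") {
  metrics <- lapply(logs, scenario_metrics, policy = policy)
  per_scenario <- do.call(rbind, lapply(metrics, metrics_row))
  rownames(per_scenario) <- NULL
  both <- all(vapply(metrics, function(m)
    all(c("first_responders", "team") %in% m$phases$phase), logical(1)))
  list(metrics = metrics, per_scenario = per_scenario,
       cohort = cohort_table(metrics, quantile_method),
       comparison = if (both) comparison_table(metrics, quantile_method)
                    else NULL)
}

.log_msg <- function(quiet, ...) if (!quiet) message(...)

.run_manifest <- function(args, seed) {
  list(command = paste(args, collapse = " "), seed = seed,
       package_version = as.character(utils::packageVersion("cprflow")),
       r_version = R.version.string, timestamp = format(Sys.time(),
         "%Y-%m-%dT%H:%M:%S%z"))
}

#' Pipeline command: generate a synthetic cohort
#'
#' Generates a cohort from a configuration (JSON overrides of
#' [generator_config()] arguments, scalar fields only) and writes the
#' event logs, manifest, ground truth and a run manifest to `out_dir`.
#'
#' @param config_path Optional path to a JSON file whose fields override
#'   `n_scenarios`, `seed`, `shockable_prob`, `conversion_prob`.
#' @param out_dir Output directory.
#' @param seed Seed override (takes precedence over the config file).
#' @param dialect Event-log dialect.
#' @param quiet Suppress progress messages.
#' @return Exit status, invisibly: 0 on success.
#' @export
cmd_generate <- function(config_path = NULL, out_dir, seed = NULL,
                         dialect = "csv", quiet = FALSE) {
  status <- tryCatch({
    over <- if (!is.null(config_path)) jsonlite::fromJSON(config_path)
            else list()
    allowed <- intersect(names(over),
                         c("n_scenarios", "seed", "shockable_prob",
                           "conversion_prob", "max_retries"))
    config <- do.call(generator_config, over[allowed])
    if (!is.null(seed)) config$seed <- seed
    cohort <- generate_cohort(config)
    write_cohort(cohort, out_dir, dialect)
    jsonlite::write_json(
      c(.run_manifest(c("generate", out_dir), config$seed),
        list(n_scenarios = config$n_scenarios)),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE,
      digits = NA)
    .log_msg(quiet, "wrote ", config$n_scenarios, " scenario logs to ",
             out_dir)
    0L
  }, error = function(e) {
    message("generate failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Pipeline command: analyze a cohort directory
#'
#' Reads every log named by `<dir>/manifest.csv`, computes per-scenario
#' metrics and writes three reports to `out_prefix`: a per-scenario
#' metrics CSV, a cohort summary CSV (percentages at 0 decimals in the
#' `display` column, full precision elsewhere) and, when all scenarios
#' have a handover, a phase-comparison CSV with the Mann-Whitney
#' p-value; plus a JSON report with full precision. Inputs are never
#' modified.
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @param policy_path Optional JSON file of [allowance_policy()]
#'   overrides.
#' @param out_prefix Path prefix for the report files.
#' @param dialect Event-log dialect.
#' @param quantile_method Quantile convention for summaries.
#' @param quiet Suppress progress messages.
#' @return Exit status, invisibly: 0 on success.
#' @export
cmd_analyze <- function(dir, policy_path = NULL, out_prefix,
                        dialect = "csv", quantile_method = "spss",
                        quiet = FALSE) {
  status <- tryCatch({
    policy <- if (!is.null(policy_path)) read_policy(policy_path)
              else allowance_policy()
    logs <- read_cohort(file.path(dir, "manifest.csv"), dialect)
    res <- analyze_cohort(logs, policy, quantile_method)
    dir.create(dirname(out_prefix), recursive = TRUE,
               showWarnings = FALSE)
    write.csv(res$per_scenario, paste0(out_prefix, "_scenarios.csv"),
              row.names = FALSE)
    write.csv(res$cohort, paste0(out_prefix, "_cohort.csv"),
              row.names = FALSE)
    if (!is.null(res$comparison))
      write.csv(res$comparison, paste0(out_prefix, "_comparison.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(cohort = res$cohort, comparison = res$comparison,
           per_scenario = res$per_scenario),
      paste0(out_prefix, "_report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    .log_msg(quiet, "analyzed ", length(logs), " scenarios; reports at ",
             out_prefix, "_*")
    0L
  }, error = function(e) {
    message("analyze failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Pipeline command: self-test of the core numerical properties
#'
#' Runs small-scale versions of the package's independent oracles: the
#' millisecond occupancy-grid check of no-flow time, the exhaustive
#' Mann-Whitney enumeration against the dynamic-programming exact test,
#' the closed-form allowance credits, and conservation of no-flow time
#' across phases and segments on generated scenarios.
#'
#' @param n_logs Number of random logs for the grid and conservation
#'   checks.
#' @param seed Seed for the generated cases.
#' @param quiet Suppress progress messages.
#' @return Exit status, invisibly: 0 iff every property holds; on
#'   failure the first failing property is named in a message.
#' @export
cmd_selftest <- function(n_logs = 50, seed = 20110, quiet = FALSE) {
  fail <- function(what) {
    message("selftest FAILED: ", what)
    invisible(1L)
  }
  pol <- allowance_policy()

  # grid oracle on small random logs (times on the 1 ms lattice)
  set.seed(seed)
  for (i in seq_len(n_logs)) {
    log <- random_test_log(duration = runif(1, 40, 120))
    nft <- no_flow_time(log, pol)
    if (abs(nft - grid_no_flow_time(log, pol)) > 1e-3 + 1e-6)
      return(fail("occupancy-grid oracle mismatch"))
    ph <- derive_phases(log)
    if (!is.null(ph$team)) {
      s <- no_flow_time(log, pol, ph$first_responders$window) +
           no_flow_time(log, pol, ph$team$window)
      if (abs(s - nft) > 1e-6)
        return(fail("phase additivity of no-flow time"))
    }
    seg <- segment_profile(log, pol)
    if (abs(sum(seg$nft_s) - nft) > 1e-6)
      return(fail("segment conservation of no-flow time"))
  }

  # exact Mann-Whitney vs exhaustive enumeration
  set.seed(seed + 1)
  for (i in seq_len(20)) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- round(rnorm(n1), 2); y <- round(rnorm(n2, 0.5), 2)
    got <- mann_whitney_exact(x, y)$p_two_sided
    want <- .mw_p_enumerate(x, y)
    if (abs(got - want) > 1e-12)
      return(fail("exact Mann-Whitney vs enumeration"))
  }

  # allowance closed forms on a constructed sparse-CPR log
  log <- closed_form_allowance_log(shocks = TRUE)
  if (abs(allowance_credit(log, pol)$credited_s - 75) > 1e-9)
    return(fail("allowance closed form with shocks (75 s)"))
  log2 <- closed_form_allowance_log(shocks = FALSE)
  if (abs(allowance_credit(log2, pol)$credited_s - 45) > 1e-9)
    return(fail("allowance closed form without shocks (45 s)"))

  .log_msg(quiet, "selftest OK (", n_logs, " random logs)")
  invisible(0L)
}

#' Random event log for oracle testing
#'
#' A simple random log, independent of the calibrated scenario
#' generator: compressions in runs separated by random pauses, all
#' times quantized to 1 ms, optionally with a handover. Intended for
#' property and oracle tests, not for emulating study conditions.
#'
#' @param duration Scenario length in seconds.
#' @param p_handover Probability of including a handover event.
#' @return An [event_log()].
#' @export
random_test_log <- function(duration = 90, p_handover = 0.7) {
  duration <- round(duration, 3)  # keep all times on the 1 ms lattice
  t <- round(runif(1, 0, 5), 3)
  comp <- numeric()
  while (t < duration) {
    run_len <- runif(1, 2, 15)
    dt <- runif(1, 0.4, 0.8)
    times <- seq(t, min(t + run_len, duration), by = dt)
    comp <- c(comp, round(times, 3))
    t <- t + run_len + runif(1, 0.2, 12)  # pause straddles the threshold
  }
  comp <- comp[comp <= duration]
  events <- data.frame(kind = c("arrest_recognized", "rosc"),
                       time = c(0, duration), detail = "")
  if (runif(1) < p_handover) {
    th <- round(runif(1, 0.3 * duration, 0.7 * duration), 3)
    events <- rbind(events, data.frame(kind = "handover", time = th,
                                       detail = ""))
  }
  event_log("random-test", comp, events)
}

#' Millisecond occupancy-grid oracle for no-flow time
#'
#' Brute-force no-flow measurement: the window is discretized into 1 ms
#' cells and a cell counts as flow iff its midpoint lies between two
#' consecutive compressions separated by at most the gap threshold.
#' Deliberately independent of the interval-merging implementation.
#'
#' @param log An [event_log()].
#' @param policy An [allowance_policy()].
#' @param window Analysis window.
#' @param step Grid step in seconds (default 0.001).
#' @return No-flow seconds measured on the grid.
#' @export
grid_no_flow_time <- function(log, policy = allowance_policy(),
                              window = c(log$t0, log$t_end),
                              step = 0.001) {
  mids <- seq(window[1] + step / 2, window[2], by = step)
  cp <- log$compressions
  if (length(cp) < 2L) return(window[2] - window[1])
  pos <- findInterval(mids, cp)
  flow <- pos >= 1L & pos < length(cp)
  idx <- which(flow)
  flow[idx] <- (cp[pos[idx] + 1L] - cp[pos[idx]]) <= policy$gap_threshold_s
  (window[2] - window[1]) - sum(flow) * step
}

#' Constructed log with known closed-form allowance credit
#'
#' A 360 s scenario of three full 2-minute cycles with abundant
#' no-flow: 60 s of continuous compressions then 60 s of pause per
#' cycle, with pulse-check and rhythm-check annotations in every pause
#' and, optionally, a shock in every cycle. With the default policy the
#' credit is exactly 3 x (10 + 5 + 10) = 75 s with shocks and
#' 3 x (10 + 5) = 45 s without.
#'
#' @param shocks Include a shock event in every cycle?
#' @return An [event_log()].
#' @export
closed_form_allowance_log <- function(shocks = TRUE) {
  comp <- numeric(); events <- data.frame(
    kind = "arrest_recognized", time = 0, detail = "")
  for (c in 0:2) {
    a <- c * 120
    comp <- c(comp, seq(a, a + 60, by = 0.5))
    events <- rbind(events,
      data.frame(kind = c("pulse_check", "rhythm_check"),
                 time = c(a + 70, a + 90), detail = ""))
    if (shocks)
      events <- rbind(events, data.frame(kind = "shock", time = a + 100,
                                         detail = "VF"))
  }
  events <- rbind(events, data.frame(kind = "scenario_end", time = 360,
                                     detail = ""))
  event_log("closed-form-allowance", comp, events)
}
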