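#' @importFrom utils read.csv write.csv head tail
#' @importFrom stats median quantile setNames pnorm qnorm qgamma
#'   rnorm rlnorm rgamma runif rbinom optim qbeta rbeta wilcox.test
NULL

# Recognised annotated-event kinds. "arrest_recognized" defines Time 0;
# "rosc" or "scenario_end" terminates the analysis horizon; "handover"
# (arrival of physician and orderlies) splits first-responder and team
# phases.
.event_kinds <- c(
  "arrest_recognized", "cpr_started", "call_placed", "defib_arrival",
  "first_rhythm", "rhythm_check", "shock", "pulse_check", "handover",
  "rosc", "scenario_end"
)

.terminal_kinds <- c("rosc", "scenario_end")

#' Construct a validated resuscitation event log
#'
#' An `event_log` is the atomic input of the pipeline: one scenario's
#' chest-compression instants plus annotated clinical events on a common
#' clock. On construction the log is normalized: times are re-based so
#' that Time 0 (recognition of arrest) is 0, compressions are sorted, and
#' the invariants below are enforced.
#'
#' Invariants: exactly one `arrest_recognized` event and exactly one
#' terminal event (`rosc` or `scenario_end`); `t0 < t_end`; all times lie
#' within `[t0, t_end]`; compression times nondecreasing.
#'
#' @param scenario_id Character scalar identifying the scenario.
#' @param compressions Numeric vector of compression downstroke instants
#'   (seconds).
#' @param events Data frame with columns `kind`, `time`, and optionally
#'   `detail` (free text, e.g. a rhythm label).
#' @return An object of class `event_log` with fields `scenario_id`,
#'   `compressions`, `events`, `t0` (always 0 after normalization) and
#'   `t_end`.
#' @examples
#' ev <- data.frame(kind = c("arrest_recognized", "rosc"), time = c(0, 300))
#' log <- event_log("demo", compressions = seq(29, 299.5, by = 0.5), events = ev)
#' log$t_end
#' @export
event_log <- function(scenario_id, compressions, events) {
  if (!is.character(scenario_id) || length(scenario_id) != 1L)
    stop("scenario_id must be a single string")
  if (is.null(events$detail)) events$detail <- ""
  events$detail[is.na(events$detail)] <- ""
  events <- events[, c("kind", "time", "detail")]
  events$kind <- as.character(events$kind)
  events$time <- as.numeric(events$time)
  compressions <- as.numeric(compressions)

  bad <- setdiff(unique(events$kind), .event_kinds)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(events$time)))
    stop("event times must be finite")
  if (any(!is.finite(compressions)))
    stop("compression times must be finite")

  n_t0 <- sum(events$kind == "arrest_recognized")
  if (n_t0 != 1L)
    stop("log must contain exactly one 'arrest_recognized' event (found ",
         n_t0, ")")
  n_term <- sum(events$kind %in% .terminal_kinds)
  if (n_term != 1L)
    stop("log must contain exactly one terminal event ('rosc' or ",
         "'scenario_end'); found ", n_term)
  if (sum(events$kind == "handover") > 1L)
    stop("log must contain at most one 'handover' event")

  t0 <- events$time[events$kind == "arrest_recognized"]
  t_end <- events$time[events$kind %in% .terminal_kinds]
  if (!(t0 < t_end))
    stop("t0 must precede the terminal event (t0 = ", t0,
         ", t_end = ", t_end, ")")

  # normalize: re-base clock so t0 = 0
  events$time <- events$time - t0
  compressions <- compressions - t0
  t_end <- t_end - t0

  if (is.unsorted(compressions))
    stop("compression times must be nondecreasing (offending index ",
         which(diff(compressions) < 0)[1] + 1L, ")")
  if (length(compressions) &&
      (min(compressions) < 0 || max(compressions) > t_end))
    stop("compression times must lie within [t0, t_end]")
  if (min(events$time) < 0 || max(events$time) > t_end)
    stop("event times must lie within [t0, t_end]")
  events <- events[order(events$time, match(events$kind, .event_kinds)), ]
  rownames(events) <- NULL

  structure(
    list(scenario_id = scenario_id, compressions = compressions,
         events = events, t0 = 0, t_end = t_end),
    class = "event_log"
  )
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> scenario ", x$scenario_id, ": ",
      length(x$compressions), " compressions, ",
      nrow(x$events), " annotated events, duration ",
      format(x$t_end, digits = 6), " s\n", sep = "")
  invisible(x)
}

.event_time <- function(log, kind, first = TRUE) {
  t <- log$events$time[log$events$kind == kind]
  if (!length(t)) return(NA_real_)
  if (first) t[1] else t[length(t)]
}

#' Read an event log from a delimited or JSON file
#'
#' The tabular dialect is a UTF-8 CSV with header
#' `time_s,event_type,detail`; `event_type` is either `"compression"` or
#' one of the annotated-event kinds. The JSON dialect carries the same
#' records as an array of objects plus a `scenario_id` field.
#'
#' @param source Path (or connection) to the file.
#' @param dialect `"csv"` or `"json"`.
#' @param scenario_id Identifier to attach; defaults to the file base
#'   name for CSV, or the embedded id for JSON.
#' @return A validated, time-normalized [event_log()].
#' @export
read_event_log <- function(source, dialect = c("csv", "json"),
                           scenario_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    rec <- read.csv(source, colClasses = c("numeric", "character",
                                           "character"))
    names(rec) <- c("time_s", "event_type", "detail")
    if (is.null(scenario_id))
      scenario_id <- if (is.character(source))
        sub("\\.[^.]*$", "", basename(source)) else "scenario"
  } else {
    obj <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
    rec <- obj$records
    if (is.null(rec$detail)) rec$detail <- ""
    if (is.null(scenario_id))
      scenario_id <- if (!is.null(obj$scenario_id)) obj$scenario_id
                     else "scenario"
  }
  is_comp <- rec$event_type == "compression"
  ev <- data.frame(kind = rec$event_type[!is_comp],
                   time = rec$time_s[!is_comp],
                   detail = rec$detail[!is_comp])
  event_log(scenario_id, compressions = rec$time_s[is_comp], events = ev)
}

#' Write an event log to a delimited or JSON file
#'
#' Emits records readable by [read_event_log()]; reading back a written
#' canonical log reproduces it exactly.
#'
#' @param log An [event_log()].
#' @param sink Output path (or connection).
#' @param dialect `"csv"` or `"json"`.
#' @return Invisibly, the path written.
#' @export
write_event_log <- function(log, sink, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  rec <- rbind(
    data.frame(time_s = log$compressions,
               event_type = rep("compression", length(log$compressions)),
               detail = rep("", length(log$compressions))),
    data.frame(time_s = log$events$time, event_type = log$events$kind,
               detail = log$events$detail)
  )
  rec <- rec[order(rec$time_s, rec$event_type != "arrest_recognized"), ]
  if (dialect == "csv") {
    # %.17g round-trips doubles exactly through read.csv
    rec$time_s <- sprintf("%.17g", rec$time_s)
    write.csv(rec, sink, row.names = FALSE, quote = 3L)
  } else {
    jsonlite::write_json(
      list(scenario_id = log$scenario_id, records = rec),
      sink, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(sink)
}

#' Split a log into analysis phases
#'
#' The overall phase always spans `[t0, t_end)`. When a `handover` event
#' (arrival of one physician and orderlies) is present, the timeline is
#' partitioned into a `first_responders` phase `[t0, handover)` and a
#' `team` phase `[handover, t_end)`; the windows are half-open, so an
#' event exactly at handover belongs to the team.
#'
#' @param log An [event_log()].
#' @return A named list of phases, each a list with `label` and `window`
#'   (numeric length-2, half-open).
#' @export
derive_phases <- function(log) {
  phases <- list(overall = list(label = "overall",
                                window = c(log$t0, log$t_end)))
  th <- .event_time(log, "handover")
  if (!is.na(th)) {
    if (th <= log$t0 || th >= log$t_end)
      stop("handover time must lie strictly inside (t0, t_end)")
    phases$first_responders <- list(label = "first_responders",
                                    window = c(log$t0, th))
    phases$team <- list(label = "team", window = c(th, log$t_end))
  }
  phases
}

#' Read a cohort of event logs from a manifest
#'
#' @param manifest Path to a CSV with columns `scenario_id,path`; `path`
#'   entries are resolved relative to the manifest's directory.
#' @param dialect Dialect of the individual log files.
#' @return Named list of [event_log()] objects.
#' @export
read_cohort <- function(manifest, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (is.character(manifest) && !file.exists(manifest))
    stop("manifest not found: ", manifest)
  man <- read.csv(manifest, colClasses = "character")
  base <- dirname(manifest)
  logs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_event_log(p, dialect = dialect, scenario_id = man$scenario_id[i])
  })
  setNames(logs, man$scenario_id)
}
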