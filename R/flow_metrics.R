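#' Pause allowance policy
#'
#' Guideline-sanctioned pause budget per advanced-life-support cycle:
#' up to 5 s for rhythm analysis, 10 s to charge the defibrillator and
#' deliver a shock (when appropriate), and 10 s for a pulse check, per
#' two-minute cycle. The policy also carries the inter-compression gap
#' threshold separating ongoing CPR from an interruption.
#'
#' @param rhythm_analysis_s Seconds credited per cycle to rhythm
#'   analysis (default 5).
#' @param shock_s Seconds credited per cycle to defibrillator charge and
#'   shock delivery, granted only in cycles containing a shock
#'   (default 10).
#' @param pulse_check_s Seconds credited per cycle to a pulse check
#'   (default 10).
#' @param cycle_s Cycle length in seconds (default 120).
#' @param gap_threshold_s Largest inter-compression gap still counted as
#'   continuous CPR, in seconds (default 1.5, the conventional
#'   interruption threshold in CPR quality research).
#' @param anchor Where allowance cycles are anchored: `"t0"` (default)
#'   or `"first_rhythm"`.
#' @return An object of class `allowance_policy`.
#' @export
allowance_policy <- function(rhythm_analysis_s = 5, shock_s = 10,
                             pulse_check_s = 10, cycle_s = 120,
                             gap_threshold_s = 1.5,
                             anchor = c("t0", "first_rhythm")) {
  anchor <- match.arg(anchor)
  vals <- c(rhythm_analysis_s = rhythm_analysis_s, shock_s = shock_s,
            pulse_check_s = pulse_check_s, cycle_s = cycle_s,
            gap_threshold_s = gap_threshold_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all policy fields must be positive and finite")
  if (rhythm_analysis_s > cycle_s || shock_s > cycle_s ||
      pulse_check_s > cycle_s)
    stop("per-cycle allowances cannot exceed the cycle length")
  structure(list(rhythm_analysis_s = rhythm_analysis_s, shock_s = shock_s,
                 pulse_check_s = pulse_check_s, cycle_s = cycle_s,
                 gap_threshold_s = gap_threshold_s, anchor = anchor),
            class = "allowance_policy")
}

#' Read an allowance policy from a YAML-like key:value or JSON file
#'
#' @param path Path to a JSON file with any subset of the
#'   [allowance_policy()] fields; missing fields take the defaults.
#' @return An `allowance_policy`.
#' @export
read_policy <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(allowance_policy, vals)
}

.check_window <- function(log, window) {
  if (length(window) != 2L || !all(is.finite(window)))
    stop("window must be a finite length-2 numeric")
  if (window[2] <= window[1])
    stop("window must be non-empty: [", window[1], ", ", window[2], ")")
  if (window[1] < log$t0 - 1e-9 || window[2] > log$t_end + 1e-9)
    stop("window [", window[1], ", ", window[2],
         ") lies outside the log span [", log$t0, ", ", log$t_end, ")")
  invisible(window)
}

#' Flow intervals: spans of ongoing chest compressions
#'
#' The flow set is built from the full compression stream: every pair of
#' consecutive compressions separated by at most `gap_threshold_s` forms
#' a flow span, abutting spans are merged, and the result is clipped to
#' the requested window. Gaps wider than the threshold, the span from
#' Time 0 to the first compression, and the span from the last
#' compression to the end of the horizon are no-flow. Clipping the
#' global flow set (rather than recomputing from compressions inside the
#' window) makes no-flow time exactly additive across phase boundaries.
#'
#' @param log An [event_log()].
#' @param policy An [allowance_policy()] (only `gap_threshold_s` is
#'   used here).
#' @param window Half-open analysis window `[start, end)`; defaults to
#'   the whole log.
#' @return An [interval_set()] of flow spans inside the window.
#' @export
flow_intervals <- function(log, policy = allowance_policy(),
                           window = c(log$t0, log$t_end)) {
  .check_window(log, window)
  cp <- log$compressions
  if (length(cp) < 2L) return(interval_set())
  gaps <- diff(cp)
  ok <- gaps <= policy$gap_threshold_s
  if (!any(ok)) return(interval_set())
  flow <- interval_set(cp[-length(cp)][ok], cp[-1L][ok])
  interval_clip(flow, window)
}

#' No-flow time within a window
#'
#' Time in the window during which no chest compressions were being
#' performed: the window duration minus the total flow time.
#'
#' @inheritParams flow_intervals
#' @return Seconds of no-flow, in `[0, window duration]`.
#' @export
no_flow_time <- function(log, policy = allowance_policy(),
                         window = c(log$t0, log$t_end)) {
  .check_window(log, window)
  dur <- window[2] - window[1]
  max(0, dur - interval_total(flow_intervals(log, policy, window)))
}

#' No-flow ratio
#'
#' The fraction of an interval with compromised circulation: no-flow
#' time divided by the interval duration. Equals 1 minus the
#' chest-compression fraction.
#'
#' @param nft No-flow time in seconds.
#' @param window_duration Interval duration in seconds (> 0).
#' @return A fraction in `[0, 1]`.
#' @export
no_flow_ratio <- function(nft, window_duration) {
  if (!is.finite(window_duration) || window_duration <= 0)
    stop("window_duration must be positive")
  if (nft < 0 || nft > window_duration + 1e-9)
    stop("nft must lie in [0, window_duration]")
  min(1, nft / window_duration)
}

# no-flow intervals of a log within a window
.no_flow_intervals <- function(log, policy, window) {
  interval_complement(flow_intervals(log, policy, window), window)
}

.cycle_anchor <- function(log, policy) {
  if (policy$anchor == "first_rhythm") {
    tr <- .event_time(log, "first_rhythm")
    if (!is.na(tr)) return(tr %% policy$cycle_s)
  }
  log$t0
}

# cycle windows of length cycle_s covering `window`, anchored at `anchor`
.cycle_windows <- function(window, cycle_s, anchor) {
  k0 <- floor((window[1] - anchor) / cycle_s)
  k1 <- ceiling((window[2] - anchor) / cycle_s) - 1
  lapply(k0:k1, function(k) {
    c(max(window[1], anchor + k * cycle_s),
      min(window[2], anchor + (k + 1) * cycle_s))
  })
}

#' Allowance credit against no-flow time
#'
#' Credits guideline-sanctioned pauses against the actual no-flow time,
#' cycle by cycle. The window is partitioned into consecutive cycles of
#' `cycle_s` anchored at Time 0. Within each cycle at most one pulse
#' check credit (<= `pulse_check_s`), one rhythm-analysis credit
#' (<= `rhythm_analysis_s`) and -- only if a shock occurs in the cycle --
#' one shock credit (<= `shock_s`) are granted, each further capped by
#' the no-flow time still uncredited in that cycle, so the total credit
#' never exceeds the actual no-flow time.
#'
#' Attribution mode per credit type: when the log annotates the
#' corresponding events (`pulse_check`, `rhythm_check`, `shock`), a
#' credit is granted only in cycles containing such an event and is
#' attached to the no-flow pause containing (or nearest to) the event,
#' additionally capped by that pause's uncredited length. When a type is
#' never annotated, a schedule-based fallback credits the per-cycle cap
#' in every cycle, up to the cycle's remaining no-flow. Shock credit
#' always requires an annotated shock ("when appropriate").
#'
#' @inheritParams flow_intervals
#' @return A list with `credited_s` (total seconds credited) and
#'   `ledger`, a data frame with one row per granted credit: `cycle`,
#'   `type`, `time` (event time, or cycle midpoint for schedule
#'   fallback), `credit_s`, `mode`.
#' @export
allowance_credit <- function(log, policy = allowance_policy(),
                             window = c(log$t0, log$t_end)) {
  .check_window(log, window)
  cycles <- .cycle_windows(window, policy$cycle_s,
                           .cycle_anchor(log, policy))
  types <- data.frame(
    type = c("pulse_check", "rhythm_analysis", "shock"),
    kind = c("pulse_check", "rhythm_check", "shock"),
    cap = c(policy$pulse_check_s, policy$rhythm_analysis_s,
            policy$shock_s)
  )
  # a type runs event-matched iff the log annotates it at least once
  types$event_matched <- vapply(
    types$kind, function(k) any(log$events$kind == k), logical(1))
  types$event_matched[types$type == "shock"] <- TRUE

  led <- list()
  for (ci in seq_along(cycles)) {
    cw <- cycles[[ci]]
    nf <- .no_flow_intervals(log, policy, cw)
    remaining <- interval_total(nf)          # uncredited no-flow in cycle
    if (remaining <= 0) next
    pause_left <- if (nrow(nf)) nf$end - nf$start else numeric()
    for (ti in seq_len(nrow(types))) {
      cap <- types$cap[ti]
      if (types$event_matched[ti]) {
        te <- log$events$time[log$events$kind == types$kind[ti] &
                              log$events$time >= cw[1] &
                              log$events$time < cw[2]]
        if (!length(te)) next
        te <- te[1]
        # pause containing the event, else nearest pause
        idx <- which(nf$start <= te & te < nf$end)
        if (!length(idx)) {
          d <- pmax(nf$start - te, te - nf$end, 0)
          idx <- which.min(d)
        }
        credit <- min(cap, pause_left[idx], remaining)
        if (credit <= 0) next
        pause_left[idx] <- pause_left[idx] - credit
        led[[length(led) + 1L]] <- data.frame(
          cycle = ci, type = types$type[ti], time = te,
          credit_s = credit, mode = "event")
      } else {
        credit <- min(cap, remaining)
        if (credit <= 0) next
        led[[length(led) + 1L]] <- data.frame(
          cycle = ci, type = types$type[ti], time = mean(cw),
          credit_s = credit, mode = "schedule")
      }
      remaining <- remaining - credit
      if (remaining <= 0) break
    }
  }
  ledger <- if (length(led)) do.call(rbind, led)
            else data.frame(cycle = integer(), type = character(),
                            time = numeric(), credit_s = numeric(),
                            mode = character())
  list(credited_s = sum(ledger$credit_s), ledger = ledger)
}

#' Adjusted no-flow metrics
#'
#' Subtracts the allowance credit from the no-flow time. The adjusted
#' no-flow time represents the avoidable time without circulation and
#' would ideally be zero under guideline-perfect performance.
#'
#' @param nft No-flow time (s).
#' @param credited Allowance credit (s), at most `nft`.
#' @param window_duration Window duration (s, > 0).
#' @return List with `nft_adj_s` and `nfr_adj`.
#' @export
adjusted_metrics <- function(nft, credited, window_duration) {
  if (credited > nft + 1e-9)
    stop("credited (", credited, ") exceeds nft (", nft,
         "): allowance ledger bug")
  nft_adj <- max(0, nft - credited)
  list(nft_adj_s = nft_adj,
       nfr_adj = no_flow_ratio(nft_adj, window_duration))
}

#' Compression rates within a window
#'
#' Two distinct rates: `rate_cpm`, the pace while actually compressing
#' (median of `60 / gap` over consecutive compression pairs whose gap is
#' within the continuity threshold), and `delivered_cpm`, the
#' compressions actually given per elapsed minute of the window. The two
#' coincide only for uninterrupted CPR.
#'
#' @inheritParams flow_intervals
#' @return List with `rate_cpm` and `delivered_cpm` (either 0 when
#'   undefined, with a warning for a degenerate window).
#' @export
compression_rates <- function(log, policy = allowance_policy(),
                              window = c(log$t0, log$t_end)) {
  .check_window(log, window)
  cp <- log$compressions[log$compressions >= window[1] &
                         log$compressions < window[2]]
  dur_min <- (window[2] - window[1]) / 60
  delivered <- length(cp) / dur_min
  gaps <- diff(cp)
  gaps <- gaps[gaps > 0 & gaps <= policy$gap_threshold_s]
  rate <- if (length(gaps) >= 2L) median(60 / gaps) else 0
  if (length(cp) == 0L)
    warning("no compressions in window [", window[1], ", ", window[2],
            "); rates reported as 0")
  list(rate_cpm = rate, delivered_cpm = delivered)
}

#' Segment no-flow profile
#'
#' Divides the scenario into consecutive half-open segments (30 s by
#' default) from Time 0, keeping a final partial segment at its true
#' length, and measures no-flow time per segment. Segment no-flow times
#' sum exactly to the overall no-flow time.
#'
#' @inheritParams flow_intervals
#' @param segment_s Segment length in seconds (default 30).
#' @return Data frame with `segment`, `start`, `end`, `nft_s`.
#' @export
segment_profile <- function(log, policy = allowance_policy(),
                            segment_s = 30) {
  if (!is.finite(segment_s) || segment_s <= 0)
    stop("segment_s must be positive")
  starts <- seq(log$t0, log$t_end, by = segment_s)
  if (starts[length(starts)] >= log$t_end)
    starts <- starts[-length(starts)]
  ends <- pmin(starts + segment_s, log$t_end)
  flow <- flow_intervals(log, policy)  # one global flow set, clipped per segment
  nft <- vapply(seq_along(starts), function(i) {
    w <- c(starts[i], ends[i])
    max(0, (w[2] - w[1]) - interval_total(interval_clip(flow, w)))
  }, numeric(1))
  data.frame(segment = seq_along(starts), start = starts, end = ends,
             nft_s = nft)
}

#' Time-to-event markers
#'
#' Times from recognition of arrest (Time 0) to initiation of CPR, to
#' arrival of the defibrillator in the room, and to the first rhythm on
#' the defibrillator. Time to CPR uses the `cpr_started` annotation when
#' present, otherwise the first compression. Markers absent from the log
#' are `NA`, never 0.
#'
#' @param log An [event_log()].
#' @return Named list `time_to_cpr_s`, `time_to_defib_arrival_s`,
#'   `time_to_first_rhythm_s`.
#' @export
time_markers <- function(log) {
  tc <- .event_time(log, "cpr_started")
  if (is.na(tc) && length(log$compressions)) tc <- log$compressions[1]
  list(time_to_cpr_s = tc - log$t0,
       time_to_defib_arrival_s = .event_time(log, "defib_arrival") - log$t0,
       time_to_first_rhythm_s = .event_time(log, "first_rhythm") - log$t0)
}

#' All per-scenario resuscitation metrics
#'
#' Computes, for the overall window and (when a handover exists) the
#' first-responder and team phases: duration, no-flow time and ratio,
#' allowance-adjusted variants, and the two compression rates; plus the
#' scenario-level time-to-event markers and the 30-second no-flow
#' segment profile.
#'
#' Per-phase adjustment attributes each ledger credit to the phase
#' containing its `time` and caps the per-phase credited total at that
#' phase's no-flow time, so `0 <= nfr_adj <= nfr` holds in every phase
#' even when an allowance cycle straddles the handover.
#'
#' @inheritParams flow_intervals
#' @param segment_s Segment length for the no-flow profile (s).
#' @return An object of class `scenario_metrics`: list with
#'   `scenario_id`, `phases` (data frame, one row per phase), `markers`,
#'   `segments`, and the full credit `ledger`.
#' @export
scenario_metrics <- function(log, policy = allowance_policy(),
                             segment_s = 30) {
  phases <- derive_phases(log)
  cred <- allowance_credit(log, policy)
  rows <- lapply(phases, function(ph) {
    w <- ph$window
    dur <- w[2] - w[1]
    nft <- no_flow_time(log, policy, w)
    in_phase <- cred$ledger$time >= w[1] & cred$ledger$time < w[2]
    credited <- min(sum(cred$ledger$credit_s[in_phase]), nft)
    adj <- adjusted_metrics(nft, credited, dur)
    rates <- suppressWarnings(compression_rates(log, policy, w))
    data.frame(phase = ph$label, duration_s = dur, nft_s = nft,
               nfr = no_flow_ratio(nft, dur), credited_s = credited,
               nft_adj_s = adj$nft_adj_s, nfr_adj = adj$nfr_adj,
               rate_cpm = rates$rate_cpm,
               delivered_cpm = rates$delivered_cpm)
  })
  phase_df <- do.call(rbind, rows)
  rownames(phase_df) <- NULL
  structure(
    list(scenario_id = log$scenario_id, phases = phase_df,
         markers = time_markers(log),
         segments = segment_profile(log, policy, segment_s),
         ledger = cred$ledger),
    class = "scenario_metrics"
  )
}

#' @export
print.scenario_metrics <- function(x, ...) {
  cat("<scenario_metrics> ", x$scenario_id, "\n", sep = "")
  df <- x$phases
  df$nfr <- sprintf("%.0f%%", 100 * df$nfr)
  df$nfr_adj <- sprintf("%.0f%%", 100 * df$nfr_adj)
  print(df, digits = 4)
  invisible(x)
}

#' Flatten scenario metrics to one row
#'
#' One row per scenario with phase-prefixed columns, suitable for a
#' cohort table or CSV export.
#'
#' @param m A `scenario_metrics` object.
#' @return A one-row data frame.
#' @export
metrics_row <- function(m) {
  out <- data.frame(scenario_id = m$scenario_id)
  for (i in seq_len(nrow(m$phases))) {
    ph <- m$phases$phase[i]
    for (col in setdiff(names(m$phases), "phase"))
      out[[paste(ph, col, sep = ".")]] <- m$phases[[col]][i]
  }
  out$time_to_cpr_s <- m$markers$time_to_cpr_s
  out$time_to_defib_arrival_s <- m$markers$time_to_defib_arrival_s
  out$time_to_first_rhythm_s <- m$markers$time_to_first_rhythm_s
  out
}
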