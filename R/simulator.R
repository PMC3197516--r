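#' Distribution specifications for the scenario generator
#'
#' Small helpers describing the marginal distributions the generator
#' draws from. Time-like quantities default to lognormals (nonnegative,
#' right-skewed) parameterized by their median and, optionally, their
#' interquartile range; no-flow-ratio targets use a Beta distribution
#' calibrated so that its median and quartiles match given values.
#'
#' @param median Target median.
#' @param q25,q75 Optional target quartiles. For the lognormal they set
#'   `sdlog = log(q75/q25) / (2 * qnorm(0.75))`; for the Beta all three
#'   quantiles are fitted numerically.
#' @param sdlog Log-scale standard deviation (lognormal), used when the
#'   quartiles are not given.
#' @param mean,sd Normal parameters.
#' @param shape Gamma shape; the rate is `shape / mean`.
#' @return A `dist_spec` list understood by [draw_dist()].
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_lognormal <- function(median, q25 = NULL, q75 = NULL, sdlog = 0.25) {
  if (!is.null(q25) && !is.null(q75))
    sdlog <- log(q75 / q25) / (2 * qnorm(0.75))
  structure(list(dist = "lognormal", meanlog = log(median),
                 sdlog = sdlog), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_beta_quantiles <- function(median, q25, q75) {
  stopifnot(0 < q25, q25 <= median, median <= q75, q75 < 1)
  # the median is weighted heavily: a two-parameter Beta cannot match
  # three asymmetric quantiles exactly, and cohort calibration is
  # anchored on the median; the quartiles absorb the residual misfit
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    q <- qbeta(c(0.25, 0.5, 0.75), a, b)
    10 * (q[2] - median)^2 + (q[1] - q25)^2 + (q[3] - q75)^2
  }
  # moment-matched start: mean ~ median, concentration from IQR width
  m <- median
  conc <- m * (1 - m) / ((q75 - q25) / 1.35)^2
  fit <- optim(log(c(m * conc, (1 - m) * conc)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  structure(list(dist = "beta", shape1 = exp(fit$par[1]),
                 shape2 = exp(fit$par[2])), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  structure(list(dist = "normal", mean = mean, sd = sd),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_gamma <- function(mean, shape = 2) {
  structure(list(dist = "gamma", shape = shape, rate = shape / mean),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  structure(list(dist = "fixed", value = value), class = "dist_spec")
}

#' Draw from a distribution specification
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1) {
  switch(spec$dist,
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    beta = rbeta(n, spec$shape1, spec$shape2),
    normal = rnorm(n, spec$mean, spec$sd),
    gamma = rgamma(n, spec$shape, spec$rate),
    fixed = rep(spec$value, n),
    stop("unknown distribution: ", spec$dist))
}

#' Median of a distribution specification
#'
#' @param spec A `dist_spec`.
#' @return The distribution's median.
#' @export
dist_median <- function(spec) {
  switch(spec$dist,
    lognormal = exp(spec$meanlog),
    beta = qbeta(0.5, spec$shape1, spec$shape2),
    normal = spec$mean,
    gamma = stats::qgamma(0.5, spec$shape, spec$rate),
    fixed = spec$value,
    stop("unknown distribution: ", spec$dist))
}

#' Configuration of the synthetic scenario generator
#'
#' The defaults emulate the timing structure of a 13-scenario cohort of
#' unannounced in-hospital arrest simulations: CPR initiated at a median
#' 29 s (IQR 22-46), defibrillator arriving at 214 s (180-254), first
#' rhythm on the scope at 311 s (283-349), a first-responder phase with
#' a no-flow-ratio target distribution of median 0.39 (0.32-0.46), and a
#' team phase built from 2-minute advanced-life-support cycles hitting a
#' no-flow-ratio target of median 0.25 (0.19-0.29), at a compression
#' rate around 117 per minute.
#'
#' @param n_scenarios Number of scenarios per cohort (default 13).
#' @param seed Base seed; each scenario derives its own stream from
#'   `(seed, index)`.
#' @param arrest_duration_s,time_to_cpr_s,handover_time_s,defib_arrival_s,first_rhythm_s
#'   `dist_spec`s for the scenario time markers (seconds).
#' @param responder_nfr_target,team_nfr_target `dist_spec`s on (0,1)
#'   for the per-phase no-flow-ratio targets.
#' @param compression_rate_cpm `dist_spec` for the compression pace.
#' @param pause_length_s `dist_spec` for unstructured pause lengths.
#' @param shockable_prob Probability the initial rhythm is shockable.
#' @param conversion_prob Per-cycle probability the rhythm state flips.
#' @param max_retries Redraw cap for infeasible draws.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_scenarios = 13, seed = 1,
    arrest_duration_s = dist_lognormal(600, sdlog = 0.20),
    time_to_cpr_s = dist_lognormal(29, 22, 46),
    handover_time_s = dist_lognormal(214, 180, 254),
    defib_arrival_s = dist_lognormal(214, 180, 254),
    first_rhythm_s = dist_lognormal(311, 283, 349),
    responder_nfr_target = dist_beta_quantiles(0.39, 0.32, 0.46),
    team_nfr_target = dist_beta_quantiles(0.25, 0.19, 0.29),
    compression_rate_cpm = dist_normal(117, 5),
    pause_length_s = dist_gamma(8, shape = 2),
    shockable_prob = 0.5, conversion_prob = 0.3,
    max_retries = 100) {
  if (n_scenarios < 1) stop("n_scenarios must be at least 1")
  if (shockable_prob < 0 || shockable_prob > 1)
    stop("shockable_prob must lie in [0, 1]")
  structure(as.list(environment()), class = "generator_config")
}

# derived per-scenario seed, kept inside 32-bit integer range
.scenario_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269) %%
             2147483629)
}

# scale positive pause lengths to a target sum, honouring a floor just
# above the continuity threshold; returns NULL when infeasible
.scale_pauses <- function(p, target, floor_s = 1.7) {
  if (target <= 0 || !length(p)) return(numeric())
  repeat {
    sc <- p * target / sum(p)
    if (all(sc >= floor_s)) return(sc)
    if (length(p) == 1L) return(NULL)
    p <- p[-which.min(p)]        # drop the smallest pause and retry
    if (sum(p) <= 0) return(NULL)
  }
}

# compressions covering [a, b] at ~dt spacing with both endpoints hit
# exactly, so the span contributes exactly b - a of flow
.run_compressions <- function(a, b, dt) {
  len <- b - a
  if (len <= 0) return(a)
  m <- max(1L, round(len / dt))
  seq(a, b, length.out = m + 1L)
}

#' Generate one synthetic arrest scenario
#'
#' Deterministic in `(config$seed, index)`. The event log contains
#' arrest recognition at time 0, a first compression at the drawn
#' time-to-CPR, a first-responder phase whose alternating compression
#' runs and pauses are constructed to hit the drawn responder no-flow
#' target, a handover, a team phase of 2-minute ALS cycles each holding
#' a pulse-check pause, a rhythm-analysis pause and (in shockable
#' cycles) a shock pause, tuned to the drawn team no-flow target, plus
#' defibrillator-arrival and first-rhythm markers and a terminal ROSC.
#'
#' @param config A [generator_config()].
#' @param index Scenario index (1-based).
#' @return List with `log` (an [event_log()]) and `truth` (the drawn
#'   ground-truth parameters, sufficient to predict every pipeline
#'   output).
#' @export
generate_scenario <- function(config, index = 1) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(.scenario_seed(config$seed, index))

  for (try in seq_len(config$max_retries)) {
    t_cpr <- draw_dist(config$time_to_cpr_s)
    handover <- draw_dist(config$handover_time_s)
    t_defib <- draw_dist(config$defib_arrival_s)
    t_rhythm <- draw_dist(config$first_rhythm_s)
    dur <- draw_dist(config$arrest_duration_s)
    r_fr <- draw_dist(config$responder_nfr_target)
    r_team <- draw_dist(config$team_nfr_target)
    rate <- draw_dist(config$compression_rate_cpm)
    ok <- t_cpr >= 1 && t_cpr + 20 <= handover &&
      handover + 150 <= dur && t_defib < t_rhythm &&
      t_rhythm < dur && rate > 60 &&
      r_fr * handover >= t_cpr &&          # responder target feasible
      r_team * (dur - handover) >= 6       # room for structured pauses
    if (ok) break
    if (try == config$max_retries)
      stop("could not draw a feasible scenario after ",
           config$max_retries, " retries")
  }
  dt <- 60 / rate

  ## ---- first-responder phase [0, handover) -------------------------
  # leading no-flow [0, t_cpr) is recognition/response time; extra
  # pauses make the phase no-flow sum to r_fr * handover exactly
  D <- r_fr * handover - t_cpr
  pauses <- numeric()
  if (D >= 1.8) {
    p <- numeric()
    while (sum(p) < D) p <- c(p, max(2, draw_dist(config$pause_length_s)))
    pauses <- .scale_pauses(p, D)
    if (is.null(pauses)) pauses <- D   # single pause (D >= 1.8)
  }
  k <- length(pauses)
  flow_fr <- handover - t_cpr - sum(pauses)
  w <- runif(k + 1, 0.5, 1.5)
  runs <- flow_fr * w / sum(w)
  comp <- numeric()
  cursor <- t_cpr
  for (i in seq_len(k + 1)) {
    comp <- c(comp, .run_compressions(cursor, cursor + runs[i], dt))
    cursor <- cursor + runs[i] + if (i <= k) pauses[i] else 0
  }

  events <- data.frame(kind = "arrest_recognized", time = 0, detail = "")
  add_event <- function(kind, time, detail = "")
    events <<- rbind(events, data.frame(kind = kind, time = time,
                                        detail = detail))
  add_event("call_placed", 0.6 * t_cpr)
  if (t_cpr > 4) add_event("pulse_check", 0.5 * t_cpr)  # responder check
  add_event("cpr_started", t_cpr)
  add_event("handover", handover)
  add_event("defib_arrival", t_defib)

  ## ---- team phase [handover, dur): 120 s ALS cycles ----------------
  team_len <- dur - handover
  team_nf <- r_team * team_len
  bounds <- seq(handover, dur, by = 120)
  if (bounds[length(bounds)] < dur) bounds <- c(bounds, dur)
  n_cyc <- length(bounds) - 1L
  cyc_len <- diff(bounds)

  shockable <- logical(n_cyc)
  shockable[1] <- runif(1) < config$shockable_prob
  if (n_cyc > 1) for (c in 2:n_cyc)
    shockable[c] <- xor(shockable[c - 1], runif(1) < config$conversion_prob)

  cursor <- handover
  first_shock_done <- FALSE
  for (c in seq_len(n_cyc)) {
    q_c <- team_nf * cyc_len[c] / team_len   # cycle no-flow budget
    struct <- c(rhythm = runif(1, 3, 5), pulse = runif(1, 6, 10))
    if (shockable[c]) struct <- c(struct, shock = runif(1, 6, 10))
    extras <- numeric()
    if (q_c > sum(struct) + 1.8) {
      while (sum(extras) < q_c - sum(struct))
        extras <- c(extras, max(2, draw_dist(config$pause_length_s)))
      extras <- .scale_pauses(extras, q_c - sum(struct))
      if (is.null(extras)) extras <- q_c - sum(struct)
    } else {
      sc <- .scale_pauses(struct, q_c)
      if (is.null(sc)) {       # budget too small even for floors: shrink
        sc <- rep(q_c / length(struct), length(struct))
        if (any(sc < 1.7)) sc <- q_c  # collapse to one combined pause
        names(sc) <- names(struct)[seq_along(sc)]
      }
      struct <- sc
    }
    all_pauses <- c(struct, unname(extras))
    kinds <- c(names(struct), rep("", length(extras)))
    ord <- seq_along(all_pauses)          # rhythm, [shock], pulse, extras
    flow_c <- cyc_len[c] - sum(all_pauses)
    wts <- runif(length(all_pauses) + 1, 0.5, 1.5)
    runs <- flow_c * wts / sum(wts)
    for (i in seq_along(runs)) {
      comp <- c(comp, .run_compressions(cursor, cursor + runs[i], dt))
      cursor <- cursor + runs[i]
      if (i <= length(all_pauses)) {
        pk <- kinds[ord[i]]
        pmid <- cursor + all_pauses[ord[i]] / 2
        lab <- if (shockable[c]) "VF" else "PEA"
        if (pk == "rhythm") add_event("rhythm_check", pmid, lab)
        if (pk == "pulse") add_event("pulse_check", pmid)
        if (pk == "shock") { add_event("shock", pmid, lab)
                             first_shock_done <- TRUE }
        cursor <- cursor + all_pauses[ord[i]]
      }
    }
  }
  add_event("first_rhythm", t_rhythm,
            if (shockable[min(n_cyc, max(1, ceiling((t_rhythm - handover) /
                                                    120)))]) "VF" else "PEA")
  add_event("rosc", dur)

  comp <- sort(comp)
  comp <- comp[c(TRUE, diff(comp) > 1e-9)]   # dedupe boundary doubles
  comp <- pmin(comp, dur)

  log <- event_log(sprintf("sim-%03d", index), comp, events)
  truth <- list(index = index, time_to_cpr_s = t_cpr,
                handover_s = handover, defib_arrival_s = t_defib,
                first_rhythm_s = t_rhythm, duration_s = dur,
                responder_nfr = r_fr, team_nfr = r_team,
                rate_cpm = rate, shockable = shockable)
  list(log = log, truth = truth)
}

#' Generate a cohort of synthetic scenarios
#'
#' @param config A [generator_config()].
#' @return List of `n_scenarios` elements, each `list(log, truth)`;
#'   reproducible from the seed and independent of generation order.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_scenarios),
         function(i) generate_scenario(config, i))
}

#' Write a generated cohort to a directory
#'
#' Writes one event-log file per scenario, a `manifest.csv`
#' (`scenario_id,path`) and a `ground_truth.csv` with the drawn
#' per-scenario parameters.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Event-log dialect, `"csv"` or `"json"`.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- dialect
  rows <- lapply(cohort, function(sc) {
    fn <- paste0(sc$log$scenario_id, ".", ext)
    write_event_log(sc$log, file.path(dir, fn), dialect)
    data.frame(scenario_id = sc$log$scenario_id, path = fn)
  })
  man <- do.call(rbind, rows)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- do.call(rbind, lapply(cohort, function(sc)
    data.frame(scenario_id = sc$log$scenario_id,
               sc$truth[setdiff(names(sc$truth),
                                c("shockable", "index"))])))
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
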