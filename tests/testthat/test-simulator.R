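test_that("generation is deterministic in (seed, index)", {
  cfg <- generator_config(seed = 12)
  a <- generate_scenario(cfg, 3)
  b <- generate_scenario(cfg, 3)
  expect_identical(a, b)
  # and byte-identical once written
  fa <- tempfile(); fb <- tempfile()
  write_event_log(a$log, fa); write_event_log(b$log, fb)
  expect_identical(readLines(fa), readLines(fb))
  unlink(c(fa, fb))

  # different index or seed changes the draw
  expect_false(identical(a$log$compressions,
                         generate_scenario(cfg, 4)$log$compressions))
  cfg2 <- generator_config(seed = 13)
  expect_false(identical(a$log$compressions,
                         generate_scenario(cfg2, 3)$log$compressions))

  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(generate_scenario(cfg, 1)); after <- runif(5)
  expect_identical(before, after)
})

test_that("generated logs hit their drawn no-flow targets", {
  cfg <- generator_config(n_scenarios = 8, seed = 201)
  for (sc in generate_cohort(cfg)) {
    m <- scenario_metrics(sc$log)
    ph <- m$phases
    fr <- ph$nfr[ph$phase == "first_responders"]
    tm <- ph$nfr[ph$phase == "team"]
    expect_close(fr, sc$truth$responder_nfr, 0.01)
    expect_close(tm, sc$truth$team_nfr, 0.01)
    # markers are reproduced exactly
    expect_close(m$markers$time_to_cpr_s, sc$truth$time_to_cpr_s, 1e-6)
    expect_close(m$markers$time_to_defib_arrival_s,
                 sc$truth$defib_arrival_s, 1e-6)
    expect_close(m$markers$time_to_first_rhythm_s,
                 sc$truth$first_rhythm_s, 1e-6)
  }
})

test_that("a fixed responder target of 0.40 is reproduced", {
  cfg <- generator_config(n_scenarios = 4, seed = 7,
                          responder_nfr_target = dist_fixed(0.40))
  for (sc in generate_cohort(cfg)) {
    m <- scenario_metrics(sc$log)
    fr <- m$phases$nfr[m$phases$phase == "first_responders"]
    expect_close(fr, 0.40, 0.01)
  }
})

test_that("vanishing pauses and instant CPR drive the ratio to zero", {
  cfg <- generator_config(
    n_scenarios = 3, seed = 7,
    time_to_cpr_s = dist_fixed(1),
    responder_nfr_target = dist_fixed(0.02),
    team_nfr_target = dist_fixed(0.03))
  for (sc in generate_cohort(cfg)) {
    m <- scenario_metrics(sc$log)
    expect_true(m$phases$nfr[m$phases$phase == "overall"] < 0.06)
  }
})

test_that("every generated log passes the event-log invariants", {
  cfg <- generator_config(seed = 31)          # default n = 13
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 13)
  for (sc in cohort) {
    log <- sc$log
    expect_s3_class(log, "event_log")
    expect_false(is.unsorted(log$compressions))
    expect_true(all(log$compressions >= 0 &
                    log$compressions <= log$t_end))
    expect_true(all(log$events$time >= 0 & log$events$time <= log$t_end))
    expect_equal(sum(log$events$kind == "arrest_recognized"), 1)
    expect_equal(sum(log$events$kind %in% c("rosc", "scenario_end")), 1)
    ph <- derive_phases(log)
    expect_named(ph, c("overall", "first_responders", "team"))
    # both rhythm annotations and cycle structure are present
    expect_true(any(log$events$kind == "pulse_check"))
    expect_true(any(log$events$kind == "rhythm_check"))
  }
})

test_that("team adjustment bites whenever ALS pauses exist", {
  cfg <- generator_config(n_scenarios = 6, seed = 83)
  for (sc in generate_cohort(cfg)) {
    m <- scenario_metrics(sc$log)
    tm <- m$phases[m$phases$phase == "team", ]
    if (tm$nft_s > 0) expect_true(tm$nfr_adj < tm$nfr)
  }
})

test_that("cohort medians recover the configured distributions", {
  cfg <- generator_config(n_scenarios = 150, seed = 59)
  cohort <- generate_cohort(cfg)
  t_cpr <- vapply(cohort, function(sc) sc$truth$time_to_cpr_s, 1)
  # drawn medians near the configured distribution median
  expect_true(abs(median(t_cpr) - 29) / 29 < 0.15)
  r_fr <- vapply(cohort, function(sc) sc$truth$responder_nfr, 1)
  expect_true(abs(median(r_fr) - 0.39) < 0.02)
  r_tm <- vapply(cohort, function(sc) sc$truth$team_nfr, 1)
  expect_true(abs(median(r_tm) - 0.25) < 0.02)
})

test_that("beta calibration reproduces the requested quartiles", {
  sp <- dist_beta_quantiles(0.39, 0.32, 0.46)
  q <- qbeta(c(0.25, 0.5, 0.75), sp$shape1, sp$shape2)
  expect_close(q[2], 0.39, 0.003)
  expect_true(max(abs(q[c(1, 3)] - c(0.32, 0.46))) < 0.01)
  # the team quartiles are asymmetric around the median; the Beta fit
  # keeps the median nearly exact and lets the quartiles take the
  # residual
  sp2 <- dist_beta_quantiles(0.25, 0.19, 0.29)
  q2 <- qbeta(c(0.25, 0.5, 0.75), sp2$shape1, sp2$shape2)
  expect_close(q2[2], 0.25, 0.003)
  expect_true(max(abs(q2[c(1, 3)] - c(0.19, 0.29))) < 0.015)
})

test_that("a written cohort reads back through the manifest", {
  cfg <- generator_config(n_scenarios = 3, seed = 3)
  cohort <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(cohort, dir)
  logs <- read_cohort(file.path(dir, "manifest.csv"))
  expect_length(logs, 3)
  expect_equal(logs[[1]]$compressions, cohort[[1]]$log$compressions)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 3)
  expect_true(all(c("responder_nfr", "team_nfr") %in% names(gt)))
  unlink(dir, recursive = TRUE)
})
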