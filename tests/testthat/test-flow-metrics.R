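test_that("uninterrupted CPR has zero no-flow time", {
  log <- log_with_silences(300)
  expect_equal(interval_total(flow_intervals(log)), 300)
  expect_equal(no_flow_time(log), 0)
  m <- scenario_metrics(log)
  expect_true(all(m$phases$nfr == 0))
  expect_true(all(m$phases$nfr_adj == 0))
})

test_that("an empty compression stream is all no-flow", {
  ev <- base_events(300)
  log <- event_log("silent", numeric(), ev)
  expect_equal(nrow(flow_intervals(log)), 0)
  expect_equal(no_flow_time(log), 300)
})

test_that("a silent span becomes no-flow of exactly its length", {
  log <- log_with_silences(300, list(c(100, 130)))
  # compressions at ...99.5, 130, 130.5...: the gap is 30.5 s
  nft <- no_flow_time(log)
  expect_close(nft, 30.5, 1e-9)
  expect_close(interval_total(flow_intervals(log)), 300 - 30.5, 1e-9)
  # agrees with the millisecond occupancy-grid brute force
  expect_close(nft, grid_no_flow_time(log), 1e-3)
})

test_that("window validation rejects empty or out-of-span windows", {
  log <- log_with_silences(300)
  expect_error(no_flow_time(log, window = c(100, 100)), "non-empty")
  expect_error(no_flow_time(log, window = c(200, 100)), "non-empty")
  expect_error(no_flow_time(log, window = c(-10, 50)), "outside")
  expect_error(no_flow_time(log, window = c(200, 400)), "outside")
})

test_that("no-flow ratio is a guarded fraction", {
  expect_equal(no_flow_ratio(0, 300), 0)
  expect_equal(no_flow_ratio(300, 300), 1)
  expect_equal(no_flow_ratio(84, 300), 0.28)
  expect_error(no_flow_ratio(10, 0), "positive")
  expect_error(no_flow_ratio(10, -5), "positive")
  expect_error(no_flow_ratio(301, 300), "nft")
})

test_that("compression rate and delivered rate split as expected", {
  # metronomic at 0.513 s spacing: both rates ~117
  log <- event_log("pace", seq(0, 300, by = 0.513), base_events(300))
  r <- compression_rates(log)
  expect_close(r$rate_cpm, 60 / 0.513, 1e-6)
  expect_close(r$delivered_cpm, length(log$compressions) / 5, 1e-6)

  # same pace but compressing only ~70% of the time: pace stays ~117,
  # delivered drops to ~82
  cp <- metronome(0, 300, rate = 117)
  cp <- cp[cp < 100 | cp >= 130]
  cp <- cp[cp < 200 | cp >= 260]
  log2 <- event_log("duty", cp, base_events(300))
  r2 <- compression_rates(log2)
  expect_close(r2$rate_cpm, 117, 0.5)
  expect_true(abs(r2$delivered_cpm - 82) < 3)

  # no compressions: zero rates with a warning
  log3 <- event_log("none", numeric(), base_events(300))
  expect_warning(r3 <- compression_rates(log3), "no compressions")
  expect_equal(r3$rate_cpm, 0)
  expect_equal(r3$delivered_cpm, 0)
})

test_that("segments tile the scenario and conserve no-flow time", {
  log <- log_with_silences(90)
  seg <- segment_profile(log)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$end - seg$start, rep(30, 3))

  log2 <- log_with_silences(100)
  seg2 <- segment_profile(log2)
  expect_equal(seg2$end - seg2$start, c(30, 30, 30, 10))

  set.seed(31)
  for (i in 1:25) {
    log <- random_test_log(duration = runif(1, 35, 150))
    seg <- segment_profile(log)
    expect_close(sum(seg$nft_s), no_flow_time(log), 1e-9)
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
})

test_that("time markers come from events or the first compression", {
  extra <- data.frame(kind = c("defib_arrival", "first_rhythm"),
                      time = c(214, 311), detail = "")
  log <- event_log("markers", metronome(29, 580),
                   base_events(600, extra = extra))
  mk <- time_markers(log)
  expect_equal(mk$time_to_cpr_s, 29)          # first compression
  expect_equal(mk$time_to_defib_arrival_s, 214)
  expect_equal(mk$time_to_first_rhythm_s, 311)

  # explicit cpr_started takes precedence; absent markers are NA
  extra2 <- data.frame(kind = "cpr_started", time = 25, detail = "")
  log2 <- event_log("markers2", metronome(29, 580),
                    base_events(600, extra = extra2))
  mk2 <- time_markers(log2)
  expect_equal(mk2$time_to_cpr_s, 25)
  expect_true(is.na(mk2$time_to_defib_arrival_s))
  expect_true(is.na(mk2$time_to_first_rhythm_s))
})

test_that("no-flow time matches the grid oracle on random logs", {
  set.seed(97)
  for (i in 1:60) {
    log <- random_test_log(duration = runif(1, 40, 120))
    expect_close(no_flow_time(log), grid_no_flow_time(log), 1e-3 + 1e-9)
  }
})

test_that("no-flow time is monotone in compressions and threshold", {
  set.seed(13)
  for (i in 1:25) {
    log <- random_test_log(duration = runif(1, 40, 100))
    nft <- no_flow_time(log)
    # inserting an extra compression never increases no-flow time
    tnew <- runif(1, 0, log$t_end)
    log2 <- log
    log2$compressions <- sort(c(log$compressions, tnew))
    expect_true(no_flow_time(log2) <= nft + 1e-9)
    # widening the continuity threshold never increases no-flow time
    wide <- allowance_policy(gap_threshold_s = 3)
    expect_true(no_flow_time(log, wide) <= nft + 1e-9)
  }
})

test_that("phase no-flow times add up to the overall no-flow time", {
  set.seed(53)
  for (i in 1:25) {
    log <- random_test_log(duration = runif(1, 40, 150), p_handover = 1)
    ph <- derive_phases(log)
    expect_close(no_flow_time(log, window = ph$first_responders$window) +
                 no_flow_time(log, window = ph$team$window),
                 no_flow_time(log), 1e-9)
  }
})

test_that("scenario metrics satisfy their structural invariants", {
  cfg <- generator_config(n_scenarios = 6, seed = 303)
  for (sc in generate_cohort(cfg)) {
    m <- scenario_metrics(sc$log)
    ph <- m$phases
    expect_true(all(ph$nfr >= 0 & ph$nfr <= 1))
    expect_true(all(ph$nfr_adj >= 0))
    expect_true(all(ph$nfr_adj <= ph$nfr + 1e-12))
    expect_true(all(ph$nft_adj_s <= ph$nft_s + 1e-12))
    expect_true(all(ph$nft_s <= ph$duration_s + 1e-12))
    ov <- ph[ph$phase == "overall", ]
    expect_close(sum(m$segments$nft_s), ov$nft_s, 1e-6)
    expect_close(sum(ph$nft_s[ph$phase != "overall"]), ov$nft_s, 1e-6)
    # overall NFR is the duration-weighted mix of the phase NFRs
    sub <- ph[ph$phase != "overall", ]
    expect_close(ov$nfr,
                 sum(sub$nfr * sub$duration_s) / sum(sub$duration_s),
                 1e-9)
  }
})
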