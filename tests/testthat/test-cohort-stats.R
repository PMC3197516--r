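test_that("summaries use the (n+1)p weighted-average quantile", {
  s <- summarize_metric(5, "single")
  expect_equal(c(s$q25, s$median, s$q75), c(5, 5, 5))
  expect_equal(s$n, 1)

  # hand computation for n = 4 under (n+1)p weighting: positions
  # 1.25, 2.5, 3.75 in the sorted sample
  s2 <- summarize_metric(c(4, 1, 3, 2), "four")
  expect_equal(c(s2$q25, s2$median, s2$q75), c(1.25, 2.5, 3.75))

  expect_error(summarize_metric(numeric()), "empty")
  expect_error(summarize_metric(c(1, NA)), "finite")

  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(sample(1:30, 1))
    s <- summarize_metric(v)
    expect_true(s$q25 <= s$median && s$median <= s$q75)
  }
})

test_that("identical samples give a two-sided p of exactly 1", {
  r <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_two_sided, 1)
  r2 <- mann_whitney_exact(rnorm(8), rnorm(8))  # any data: p <= 1
  expect_true(r2$p_two_sided <= 1 && r2$p_two_sided > 0)
  expect_error(mann_whitney_exact(numeric(), 1:3), "nonempty")
})

test_that("complete separation at n = 13 vs 13 hits the closed form", {
  x <- 1:13
  y <- 14:26
  r <- mann_whitney_exact(x, y)
  expect_equal(r$method, "exact")
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 2 / choose(26, 13), tolerance = 1e-12)
  # label exchange gives the same p with the mirrored U
  r2 <- mann_whitney_exact(y, x)
  expect_equal(r2$u_statistic, 169)
  expect_equal(r2$p_two_sided, r$p_two_sided)
})

test_that("exact p equals exhaustive enumeration for small samples", {
  set.seed(17)
  for (i in 1:40) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    x <- rnorm(n1); y <- rnorm(n2, 1)     # continuous: no ties
    r <- mann_whitney_exact(x, y)
    expect_equal(r$method, "exact")
    # independent oracle: enumerate all choose(n1+n2, n1) labelings
    pooled <- c(x, y)
    rk <- rank(pooled)
    us <- apply(utils::combn(n1 + n2, n1), 2, function(ii)
      sum(rk[ii]) - n1 * (n1 + 1) / 2)
    u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    p_enum <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    expect_equal(r$p_two_sided, p_enum, tolerance = 1e-12)
  }
})

test_that("exact p agrees with the reference implementation", {
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.8)
    r <- mann_whitney_exact(x, y)
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(r$u_statistic, unname(w$statistic))
    expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-12)
  }
})

test_that("ties are handled by midranks and exact enumeration", {
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 3, 4)
  r <- mann_whitney_exact(x, y)
  expect_equal(r$method, "exact")          # enumeration under ties
  # U from midranks
  rk <- rank(c(x, y))
  expect_equal(r$u_statistic, sum(rk[1:4]) - 10)
  # U_x + U_y = n1 * n2 with midranks
  r2 <- mann_whitney_exact(y, x)
  expect_equal(r$u_statistic + r2$u_statistic, 16)
  expect_equal(r$p_two_sided, r2$p_two_sided)

  set.seed(29)
  for (i in 1:20) {
    x <- sample(1:4, sample(2:6, 1), replace = TRUE)
    y <- sample(1:4, sample(2:6, 1), replace = TRUE)
    r <- mann_whitney_exact(x, y)
    rr <- mann_whitney_exact(y, x)
    expect_equal(r$u_statistic + rr$u_statistic,
                 length(x) * length(y))
    expect_equal(r$p_two_sided, rr$p_two_sided)
  }
})

test_that("normal approximation is consistent with the exact test", {
  set.seed(41)
  x <- rnorm(50)
  y <- rnorm(50, 0.45)
  exact <- mann_whitney_exact(x, y, exact_limit = 100)
  approx <- mann_whitney_exact(x, y, exact_limit = 0)
  expect_equal(exact$method, "exact")
  expect_equal(approx$method, "normal_approx")
  expect_true(abs(exact$p_two_sided - approx$p_two_sided) < 0.01)
})

test_that("phase comparison summarizes both groups and tests them", {
  cfg <- generator_config(n_scenarios = 8, seed = 55)
  metrics <- lapply(generate_cohort(cfg),
                    function(sc) scenario_metrics(sc$log))
  cmp <- compare_phases(metrics, "nfr")
  expect_equal(cmp$first_responders$n, 8)
  expect_equal(cmp$team$n, 8)
  expect_equal(cmp$test$n1, 8)
  expect_equal(cmp$test$n2, 8)
  expect_true(cmp$test$p_two_sided > 0 && cmp$test$p_two_sided <= 1)

  # paired extension is off by default, present on request
  expect_null(cmp$paired_test)
  cmp2 <- compare_phases(metrics, "nfr", paired = TRUE)
  expect_s3_class(cmp2$paired_test, "htest")

  # a scenario without a handover is named in the error
  solo <- scenario_metrics(log_with_silences(200))
  solo$scenario_id <- "no-handover"
  expect_error(compare_phases(c(metrics, list(solo)), "nfr"),
               "no-handover")

  # identical phase values give p = 1
  fake <- lapply(1:5, function(i) {
    m <- metrics[[1]]
    m$phases$nfr <- c(0.3, 0.2 + i / 100, 0.2 + i / 100)
    m
  })
  expect_equal(compare_phases(fake, "nfr")$test$p_two_sided, 1)
})

test_that("cohort tables mirror the quality-marker layout", {
  cfg <- generator_config(n_scenarios = 5, seed = 77)
  metrics <- lapply(generate_cohort(cfg),
                    function(sc) scenario_metrics(sc$log))
  tab <- cohort_table(metrics)
  expect_equal(nrow(tab), 7)
  expect_true(all(c("NFR (%)", "NFR_adj (%)") %in% tab$metric))
  expect_true(all(tab$q25 <= tab$median & tab$median <= tab$q75))
  cmp <- comparison_table(metrics)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  expect_true(all(cmp$fr_median > cmp$team_median))
})
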