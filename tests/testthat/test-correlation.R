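test_that("percent_increase reproduces the worked drift values", {
  expect_equal(round(abs(percent_increase(-0.29, -0.36)), 1), 24.1)
  expect_equal(percent_increase(0.5, 0.5), 0)
  expect_error(percent_increase(0, 1), class = "rsvstab_error_baseline")

  # closed form: percent_increase(u, c*u) = (c - 1) * 100
  for (u in c(-3, -0.2, 0.04, 7)) {
    for (c_ in c(-2, 0.5, 1, 4.25)) {
      expect_equal(percent_increase(u, c_ * u), (c_ - 1) * 100)
    }
  }
})

test_that("interval_delta takes the smaller-magnitude endpoint as baseline", {
  cases <- list(
    list(a = -0.23, b = -0.42, abs_delta = 82.6),
    list(a = 0.04, b = 0.29, abs_delta = 625),
    list(a = 0.09, b = 0.26, abs_delta = 188.9),
    list(a = 0.04, b = 0.11, abs_delta = 175),
    list(a = 0.04, b = 0.06, abs_delta = 50),
    list(a = 0.10, b = 0.11, abs_delta = 10)
  )
  for (cs in cases) {
    d <- interval_delta(cs$a, cs$b)
    expect_equal(round(d$abs_delta_pct, 1), cs$abs_delta)
    # order of endpoints is irrelevant
    expect_equal(interval_delta(cs$b, cs$a)$abs_delta_pct, d$abs_delta_pct)
    expect_equal(abs(d$u0), min(abs(cs$a), abs(cs$b)))
  }
})

test_that("perfect linear and anti-rank relations give flat unit traces", {
  ext <- tibble::tibble(unit = sprintf("S%02d", 1:6), value = c(5, 10, 20, 40, 80, 160))
  # each day's RSVs an exact increasing linear function of ext rank
  m <- sapply(1:4, function(j) seq(10, 90, length.out = 6) + j)
  pm <- make_pm(m)
  tr <- correlation_by_day(pm, ext, method = "spearman")
  expect_equal(tr$per_day$coefficient, rep(1, 4))
  expect_equal(tr$delta_pct, 0)

  rev_ext <- tibble::tibble(unit = ext$unit, value = rev(ext$value))
  tr2 <- correlation_by_day(pm, rev_ext, method = "spearman")
  expect_equal(tr2$per_day$coefficient, rep(-1, 4))

  # pearson is invariant under positive affine transforms of ext
  trp <- correlation_by_day(pm, ext, method = "pearson")
  ext_aff <- tibble::tibble(unit = ext$unit, value = 3 * ext$value + 7)
  expect_equal(correlation_by_day(pm, ext_aff, method = "pearson")$per_day,
               trp$per_day)
  # spearman under any strictly monotone transform
  ext_mono <- tibble::tibble(unit = ext$unit, value = log(ext$value))
  expect_equal(correlation_by_day(pm, ext_mono, method = "spearman")$per_day,
               tr$per_day)
})

test_that("days with too few joined units or constant values are skipped", {
  ext <- tibble::tibble(unit = c("S01", "S02", "S03", "S04"),
                        value = c(1, 2, 3, 4))
  m <- rbind(c(10, NA, 50, 50), c(20, 30, 60, 50), c(30, NA, 70, 50), c(40, 99, 80, 50))
  # day 2 joins only 2 units; day 4 is constant in RSV
  tr <- correlation_by_day(make_pm(m), ext, method = "pearson")
  expect_equal(nrow(tr$per_day), 2L)
  expect_equal(nrow(tr$skipped_days), 2L)
  expect_match(tr$skipped_days$reason[1], "2 units")
  expect_match(tr$skipped_days$reason[2], "constant")

  # unit joining is case-insensitive and whitespace-trimmed
  ext_messy <- tibble::tibble(unit = c(" s01", "S02 ", "s03", "S04"),
                              value = c(1, 2, 3, 4))
  expect_equal(correlation_by_day(make_pm(m), ext_messy, method = "pearson")$per_day,
               tr$per_day)

  never <- make_pm(rbind(c(NA, 1), c(2, NA), c(3, 4)))
  expect_error(
    correlation_by_day(never, tibble::tibble(unit = c("S01", "S02"), value = 1:2)),
    class = "rsvstab_error_insufficient_overlap")
})

test_that("outlier days are flagged by the median +/- k MAD rule", {
  tr <- make_trace(c(0.10, 0.11, 0.10, 0.11, 0.04))
  fl <- flag_outlier_days(tr)
  expect_equal(length(fl$outlier_days), 1L)
  expect_equal(fl$per_day$coefficient[fl$per_day$date %in% fl$outlier_days], 0.04)
  expect_equal(fl$trimmed_range, c(0.10, 0.11))
  expect_equal(round(fl$trimmed_abs_delta_pct, 1), 10)
  expect_equal(round(fl$abs_delta_pct, 1), 175) # raw range [0.04, 0.11]

  # constant coefficients: no outliers
  fl0 <- flag_outlier_days(make_trace(rep(0.5, 6)))
  expect_equal(length(fl0$outlier_days), 0L)

  # evenly spaced coefficients: direct MAD oracle says none at k = 3
  ev <- seq(0.1, 0.6, by = 0.1)
  expect_true(all(abs(ev - median(ev)) <= 3 * mad(ev)))
  expect_equal(length(flag_outlier_days(make_trace(ev))$outlier_days), 0L)

  # trimming never widens the range
  for (seed in 1:10) {
    set.seed(seed)
    co <- round(runif(8, -1, 1), 2)
    if (min(abs(range(co))) == 0) co[co == 0] <- 0.01
    fl <- flag_outlier_days(make_trace(co))
    expect_gte(fl$trimmed_range[1], fl$range[1])
    expect_lte(fl$trimmed_range[2], fl$range[2])
  }

  # fewer than 5 retained days: notice, not an error, trace unchanged
  short <- make_trace(c(0.1, 0.2, 0.3))
  expect_message(out <- flag_outlier_days(short), "skipped")
  expect_equal(length(out$outlier_days), 0L)
  expect_null(out$trimmed_range)
})

test_that("traces from the generator are deterministic under a fixed seed", {
  truth <- synthetic_truth(n_units = 20, n_days = 19,
                           mu = seq(86, 100, length.out = 20),
                           sigma = seq(1.3, 2.1, length.out = 20),
                           anomaly_prob = 0.10, seed = 42)
  ext <- synthetic_external(truth)
  t1 <- correlation_by_day(simulate_pulls(truth), ext, method = "spearman")
  t2 <- correlation_by_day(simulate_pulls(truth), ext, method = "spearman")
  expect_identical(t1$per_day, t2$per_day)
  expect_gt(length(unique(t1$per_day$coefficient)), 1L) # day-to-day variation
})
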