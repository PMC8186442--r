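bari <- c(94, 98, 94, 94, 97, 95, 94, 96, 94, 95, 91, 91, 94)
bologna <- c(94, 92, 96, 94, 96, 95, 95, 96, 95, 94, 90, 91, 94)

test_that("per-series summaries match direct arithmetic", {
  st <- summarize_series(drop_anomalous(load_fixture("table2")))
  b <- st[st$unit == "Bari", ]
  # oracle: explicit formulas on the printed values
  mu <- sum(bari) / length(bari)
  s <- sqrt(sum((bari - mu)^2) / (length(bari) - 1))
  expect_equal(b$n, 13L)
  expect_equal(b$mean, mu)
  expect_equal(b$sd, s)
  expect_equal(b$sem, s / sqrt(13))
  expect_equal(b$ci_low, mu - 1.96 * s / sqrt(13))
  expect_equal(b$ci_high, mu + 1.96 * s / sqrt(13))
})

test_that("the zero-variance and short-series edge cases are honoured", {
  milan <- summarize_series(load_fixture("table5"))
  m <- milan[milan$unit == "Milan", ]
  expect_equal(m$n, 11L)
  expect_equal(m$mean, 100)
  expect_equal(m$sd, 0)
  expect_equal(m$sem, 0)
  expect_equal(c(m$ci_low, m$ci_high), c(100, 100))
  expect_true(is.na(m$shapiro_p))
  expect_true(is.na(m$non_normal))

  const <- summarize_series(make_pm(matrix(50, 1, 3)))
  expect_equal(const$mean, 50)
  expect_equal(const$sd, 0)
  expect_true(is.na(const$shapiro_p))

  single <- summarize_series(make_pm(rbind(c(40, NA), c(50, 60))))
  expect_true(is.na(single$sd[1]))
  expect_true(is.na(single$sem[1]))

  none <- make_pm(rbind(c(NA, NA), c(50, 60)))
  expect_error(summarize_series(none), class = "rsvstab_error_contract")
  expect_error(summarize_series(none), "S01")
})

test_that("normality screening uses the Shapiro-Wilk p at alpha", {
  skewed <- c(80, 80, 80, 80, 80, 80, 80, 80, 100, 100)
  st <- summarize_series(make_pm(rbind(skewed, rnorm(10, 50, 1) + 0)))
  expect_equal(st$shapiro_p[1], shapiro.test(skewed)$p.value)
  expect_true(st$non_normal[1])
  ci <- st[2, ]
  expect_true(ci$ci_low <= ci$mean && ci$mean <= ci$ci_high)
})

test_that("welch_pair follows the |t| = |mean gap| / sigma-tilde formula", {
  st <- summarize_series(drop_anomalous(load_fixture("table2")))
  a <- st[st$unit == "Bari", ]; b <- st[st$unit == "Bologna", ]
  pr <- welch_pair(a, b)
  # oracle: direct evaluation from the printed rows
  sem_a <- sd(bari) / sqrt(13); sem_b <- sd(bologna) / sqrt(13)
  expect_equal(pr$sigma_tilde, sqrt(sem_a^2 + sem_b^2))
  expect_equal(pr$t, abs(mean(bari) - mean(bologna)) / sqrt(sem_a^2 + sem_b^2))
  expect_true(pr$confident == (pr$t < 1.5))

  # symmetry
  pr2 <- welch_pair(b, a)
  expect_equal(pr2$t, pr$t)
  expect_equal(pr2$sigma_tilde, pr$sigma_tilde)

  # identity: a series against itself
  self <- welch_pair(a, a)
  expect_equal(self$t, 0)
  expect_true(self$confident)

  # degenerate variances
  z1 <- summarize_series(make_pm(matrix(100, 1, 5)))
  z2 <- summarize_series(make_pm(matrix(90, 1, 5)))
  degen <- welch_pair(z1, z2)
  expect_equal(degen$t, Inf)
  expect_false(degen$confident)
  expect_equal(welch_pair(z1, z1)$t, 0)

  short <- summarize_series(make_pm(rbind(c(40, NA, NA), c(50, 60, 70))))
  expect_error(welch_pair(short[1, ], short[2, ]),
               class = "rsvstab_error_insufficient_data")
  expect_error(welch_pair(short[1, ], short[2, ]), "S01")
})

test_that("t is scale-invariant and monotone in the mean gap", {
  set.seed(42)
  base <- matrix(runif(20, 20, 60), nrow = 2)
  for (c_ in c(0.5, 1.6)) {
    t0 <- confidence_report(make_pm(base))$pairs$t
    t1 <- confidence_report(make_pm(base * c_))$pairs$t
    expect_equal(t1, t0, tolerance = 1e-12)
  }
  # fixed sems, growing gap
  st <- summarize_series(make_pm(rbind(runif(10, 40, 50), runif(10, 40, 50))))
  ts <- sapply(c(0, 5, 10, 20), function(shift) {
    b <- st[2, ]; b$mean <- st[1, ]$mean + shift
    welch_pair(st[1, ], b)$t
  })
  expect_true(all(diff(ts) > 0))
})

test_that("confidence_report verdicts match designed cluster geometries", {
  # two clusters of 3: within-cluster means identical (permuted values),
  # cluster levels 20 vs 80, within-cluster sd 1, n = 10 pulls
  vals <- seq(-1.5, 1.5, length.out = 10)
  m <- rbind(20 + vals, 20 + rev(vals), 20 + sample(vals),
             80 + vals, 80 + rev(vals), 80 + sample(vals))
  cr <- confidence_report(make_pm(m))
  expect_equal(nrow(cr$pairs), 15L)
  # brute-force oracle on all 15 pairs
  oracle <- brute_confidence(m)
  expect_equal(cr$fractions$confident_fraction, oracle$fractions)
  expect_equal(cr$fractions$confident_fraction, rep(2 / 5, 6))
  expect_true(cr$dataset_unreliable)

  # total separation: gaps >> sigma-tilde
  sep <- make_pm(rbind(10 + vals / 10, 40 + vals / 10, 70 + vals / 10))
  crs <- confidence_report(sep)
  expect_equal(crs$fractions$confident_fraction, rep(0, 3))
  expect_false(crs$dataset_unreliable)

  # total coincidence: copies of one series
  cop <- make_pm(matrix(rep(50 + vals, 4), nrow = 4, byrow = TRUE))
  crc <- confidence_report(cop)
  expect_equal(crc$fractions$confident_fraction, rep(1, 4))
  expect_true(crc$dataset_unreliable)

  expect_error(confidence_report(make_pm(matrix(50, 1, 4))),
               class = "rsvstab_error_insufficient_data")
  expect_error(confidence_report(make_pm(rbind(c(10, NA, NA), c(20, 30, 40)))),
               class = "rsvstab_error_insufficient_data")
})

test_that("confidence_report equals the brute-force oracle on random matrices", {
  for (seed in 1:40) {
    pm <- random_small_pm(seed)
    cr <- confidence_report(pm)
    oracle <- brute_confidence(rsvstab:::rsv_matrix(pm))
    expect_equal(cr$fractions$confident_fraction, oracle$fractions)
    expect_equal(cr$dataset_unreliable, oracle$unreliable)
  }
})
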