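test_that("viability percentages follow the CFU/hemocytometer formula", {
  expect_equal(viabilityPercent(2e8, 2e8), 100)
  expect_equal(viabilityPercent(0, 2e8), 0)
  expect_equal(viabilityPercent(2e4, 2e8), 0.01)  # ~0.01% without the acid
  expect_equal(viabilityPercent(2e6, 2e8), 1)     # ~1% with it
  expect_error(viabilityPercent(10, 0), "positive")
  expect_error(viabilityPercent(-1, 10), "non-negative")
  expect_warning(viabilityPercent(3e8, 2e8), "check units")
  expect_equal(suppressWarnings(viabilityPercent(3e8, 2e8)), 100)  # clamped
})

test_that("curves normalize per replicate and report SEM across replicates", {
  days <- c(1, 5, 10, 20)
  S <- c(1, 0.8, 0.4, 0.05)
  mk <- function(rep, scale) data.frame(
    strain = "s", replicate = rep, day = days,
    total_cells_per_ml = 2e8,
    viable_cells_per_ml = 2e8 * S * scale)
  # three identical replicates (up to a per-replicate scale the
  # normalization removes): SEM is exactly zero
  rec <- rbind(mk("a", 1), mk("b", 0.5), mk("c", 2))
  cv <- buildSurvivalCurve(rec)
  expect_equal(viability(cv), 100 * S)
  expect_equal(curveSEM(cv), rep(0, 4))
  expect_equal(cv@nReplicates, 3L)

  # single replicate: SEM undefined, reported as NA
  cv1 <- buildSurvivalCurve(mk("a", 1))
  expect_true(all(is.na(curveSEM(cv1))))

  expect_error(buildSurvivalCurve(rec, referenceDay = 3),
               "not a sampled day")
  recMix <- rbind(rec, transform(mk("a", 1), strain = "t"))
  expect_error(buildSurvivalCurve(recMix), "strains")
  expect_equal(viability(buildSurvivalCurve(recMix, strain = "t")), 100 * S)
})

test_that("normalization is idempotent", {
  days <- c(1, 5, 10, 20)
  S <- c(1, 0.7, 0.2, 0.02)
  rec <- data.frame(strain = "s", replicate = "a", day = days,
                    total_cells_per_ml = 1e8,
                    viable_cells_per_ml = 1e8 * S)
  cv <- buildSurvivalCurve(rec)
  rec2 <- data.frame(strain = "s", replicate = "a", day = curveDays(cv),
                     total_cells_per_ml = 100,
                     viable_cells_per_ml = viability(cv))
  expect_equal(viability(buildSurvivalCurve(rec2)), viability(cv))
})

test_that("mean CLS is the area under the curve, max CLS the 10% crossing", {
  # step curve: 100% until day 15, then (essentially) instantaneous drop
  cvStep <- SurvivalCurve(c(0, 5, 15, 15.001, 30),
                          c(100, 100, 100, 0, 0))
  ls <- lifespanSummary(cvStep)
  expect_equal(meanCLS(ls), 15, tolerance = 1e-3)
  expect_equal(maxCLS(ls), 15, tolerance = 1e-3)
  expect_false(ls@maxCensored)

  # exponential decay at rate r on a dense grid: mean CLS ~ 1/r
  r <- 0.2
  d <- seq(0, 60, by = 0.25)
  cvExp <- SurvivalCurve(d, 100 * exp(-r * d))
  expect_equal(meanCLS(lifespanSummary(cvExp)), 1 / r, tolerance = 0.01)

  # curve never below threshold: right-censored at the last day
  cvHigh <- SurvivalCurve(c(0, 10, 20), c(100, 90, 80))
  lsHigh <- lifespanSummary(cvHigh)
  expect_true(lsHigh@maxCensored)
  expect_equal(maxCLS(lsHigh), 20)

  # a pointwise-dominating curve yields larger mean and max CLS
  d2 <- c(0, 5, 10, 20, 30)
  lo <- lifespanSummary(SurvivalCurve(d2, c(100, 70, 40, 8, 1)))
  hi <- lifespanSummary(SurvivalCurve(d2, c(100, 90, 70, 30, 5)))
  expect_gt(meanCLS(hi), meanCLS(lo))
  expect_gt(maxCLS(hi), maxCLS(lo))
})

test_that("identical curves give a log-rank statistic of 0 and p exactly 1", {
  d <- c(1, 5, 10, 15, 20, 30)
  a <- SurvivalCurve(d, c(100, 95, 60, 25, 8, 1), strain = "A")
  b <- SurvivalCurve(d, c(100, 95, 60, 25, 8, 1), strain = "B")
  lr <- logrankTest(a, b)
  expect_equal(unname(lr$statistic), 0)
  expect_identical(lr$p.value, 1)
})

test_that("the pseudo-count log-rank matches survdiff on equivalent cohorts", {
  days <- 0:5
  N <- 20
  deathsA <- c(3, 5, 4, 0, 8)   # complete follow-up
  deathsB <- c(1, 2, 0, 7, 6)   # 4 censored at day 5
  cvA <- kmCurveFromDeaths(days, deathsA, N, "A")
  cvB <- kmCurveFromDeaths(days, deathsB, N, "B")
  lr <- logrankTest(cvA, cvB, effectiveN = N)

  ind <- rbind(cbind(individualsFromDeaths(days, deathsA, N), grp = "A"),
               cbind(individualsFromDeaths(days, deathsB, N), grp = "B"))
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp, data = ind)
  expect_equal(unname(lr$statistic), unname(sd$chisq), tolerance = 1e-10)
  expect_equal(lr$p.value,
               stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("log-rank is symmetric, grid-checked, and powered for separation", {
  d <- c(1, 4, 8, 12, 16, 20, 25, 30)
  a <- lawCurve(d, 12, strain = "A")
  b <- lawCurve(d, 24, strain = "B")
  ab <- logrankTest(a, b)
  ba <- logrankTest(b, a)
  expect_equal(unname(ab$statistic), unname(ba$statistic))
  expect_equal(ab$p.value, ba$p.value)
  expect_lt(ab$p.value, 0.05)

  expect_error(logrankTest(a, lawCurve(d * 2, 24)), "day grid")
  flat <- SurvivalCurve(d, rep(100, length(d)))
  expect_error(logrankTest(flat, flat), "degenerate")

  # synthetic separated strains are detected end to end
  rec <- generateCounts(SyntheticSurvivalSpec(), seed = 99)
  wt <- buildSurvivalCurve(rec, strain = "WT")
  mut <- buildSurvivalCurve(rec, strain = "mutant")
  expect_lt(logrankTest(wt, mut)$p.value, 0.05)
})

test_that("the Welch t-test applies degenerate conventions and matches hand computation", {
  expect_identical(tTestUnpaired(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
  expect_identical(tTestUnpaired(c(2, 2, 2), c(9, 9, 9))$p.value, 0)
  expect_lt(tTestUnpaired(c(1, 2, 3), c(1001, 1002, 1003))$p.value, 1e-6)

  a <- c(19.8, 21.2, 20.4, 19.9)
  b <- c(17.5, 18.1, 17.9)
  # Welch statistic and Satterthwaite df computed from first principles
  sa2 <- var(a) / length(a)
  sb2 <- var(b) / length(b)
  tStat <- (mean(a) - mean(b)) / sqrt(sa2 + sb2)
  df <- (sa2 + sb2)^2 /
    (sa2^2 / (length(a) - 1) + sb2^2 / (length(b) - 1))
  pHand <- 2 * stats::pt(-abs(tStat), df)
  got <- tTestUnpaired(a, b)
  expect_equal(unname(got$statistic), tStat, tolerance = 1e-12)
  expect_equal(got$p.value, pHand, tolerance = 1e-12)

  expect_error(tTestUnpaired(1, c(1, 2)), "n >= 2")
})
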