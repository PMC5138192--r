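test_that("growth preserves composition and accrues Poisson mutants", {
  cfg <- SimulationConfig(cultureVolume = 1)
  prot <- SelectionProtocol(1e-8)

  # no mutation: composition preserved exactly
  set.seed(1)
  st <- growToStationary(PopulationState(1e5), cfg, SelectionProtocol(0))
  expect_equal(st@mutantCount, 0)
  expect_equal(st@wtCount, 2e8)
  expect_identical(st@phase, "stationary")

  # all-mutant inoculum stays all-mutant (mutants do not back-mutate)
  st2 <- growToStationary(PopulationState(0, 1e5), cfg, prot)
  expect_equal(st2@wtCount, 0)
  expect_equal(st2@mutantCount, 2e8)

  # new mutants are Poisson with mean mu * G * N (checked over replicates)
  set.seed(42)
  draws <- replicate(1000,
    growToStationary(PopulationState(1e5), cfg, prot)@mutantCount)
  m <- 1e-8 * 45 * 2e8  # 90
  expect_lt(abs(mean(draws) - m), 3 * sqrt(m / 1000))
  expect_lt(abs(var(draws) - m), 5 * m * sqrt(2 / 1000) * 2)

  expect_error(growToStationary(st, cfg, prot), "phase 'inoculated'")
})

test_that("death phase survival is binomial with the capped mutant bonus", {
  cfg <- SimulationConfig(wtDeathSurvival = 1e-4)
  st <- PopulationState(1e6, 0, phase = "stationary")
  set.seed(7)
  surv <- replicate(300, deathPhase(st, cfg)@wtCount)
  expect_lt(abs(mean(surv) - 100), 3 * sqrt(100 / 300))

  # survival multiplier capped at probability 1: every mutant survives
  cfgCap <- SimulationConfig(wtDeathSurvival = 1e-2,
                             mutantSurvivalMultiplier = 100)
  stM <- PopulationState(0, 5000, phase = "stationary")
  expect_equal(deathPhase(stM, cfgCap)@mutantCount, 5000)

  # expected per-step odds multiplication ~ multiplier when uncapped
  cfgE <- SimulationConfig(wtDeathSurvival = 1e-4,
                           mutantSurvivalMultiplier = 100)
  stMix <- PopulationState(1e8, 1e4, phase = "stationary")
  set.seed(11)
  odds <- replicate(300, {
    d <- deathPhase(stMix, cfgE)
    d@mutantCount / d@wtCount
  })
  expect_equal(mean(odds) / (1e4 / 1e8), 100, tolerance = 0.05)

  expect_error(deathPhase(PopulationState(10), cfg), "phase 'stationary'")
})

test_that("colony sampling is binomial at the survivor mutant fraction", {
  mk <- function(wt, mut) PopulationState(wt, mut, phase = "post_death")
  expect_equal(sampleColonies(mk(1000, 0)), 0)
  expect_equal(sampleColonies(mk(0, 1000)), 10)
  set.seed(3)
  draws <- replicate(2000, sampleColonies(mk(550, 450)))
  expect_lt(abs(mean(draws) - 4.5), 3 * sqrt(10 * 0.45 * 0.55 / 2000))
  expect_error(sampleColonies(mk(4, 2)), "extinct")
})

test_that("ensemble means track the closed form and detection the model", {
  cfg <- SimulationConfig(nReplicates = 400)
  prot <- SelectionProtocol(1e-8)
  ex <- runSelectionExperiment(cfg, prot, seed = 19)
  s <- ensembleSummary(ex)
  z <- (s$mean_odds - s$closed_form_raw) / s$se_odds
  expect_true(all(abs(z) < 4))
  # mutant fraction grows in expectation across steps
  expect_true(all(diff(s$mean_fraction) > 0))
  expect_true(all(s$mean_fraction >= 0 & s$mean_fraction <= 1))
  # detection rare at step 1, near-certain by step 3
  expect_lt(s$detection_rate[1], 0.01)
  expect_gt(s$detection_rate[3], 0.9)
})

test_that("a mutation rate of zero yields all-zero mutant trajectories", {
  ex <- runSelectionExperiment(SimulationConfig(nReplicates = 20),
                               SelectionProtocol(0), seed = 5)
  expect_true(all(replicateTrajectories(ex)$mutant_count == 0))
  expect_true(all(replicateTrajectories(ex)$mutant_colonies == 0))
})

test_that("the simulator is seed-deterministic and seed-sensitive", {
  cfg <- SimulationConfig(nReplicates = 60)
  prot <- SelectionProtocol(1e-8)
  a <- runSelectionExperiment(cfg, prot, seed = 123)
  b <- runSelectionExperiment(cfg, prot, seed = 123)
  expect_identical(replicateTrajectories(a), replicateTrajectories(b))

  c <- runSelectionExperiment(cfg, prot, seed = 124)
  expect_false(identical(replicateTrajectories(a),
                         replicateTrajectories(c)))
  # distributions from different seeds agree (KS on step-3 fractions)
  f1 <- subset(replicateTrajectories(a), step == 3)$mutant_fraction
  f2 <- subset(replicateTrajectories(c), step == 3)$mutant_fraction
  expect_gt(suppressWarnings(stats::ks.test(f1, f2)$p.value), 0.01)
})

test_that("cultures falling below the colony panel are flagged extinct", {
  # tiny culture volume + harsh survival: a 2000-cell stationary culture
  # leaves ~2 survivors, below the 10-colony panel
  cfg <- SimulationConfig(wtDeathSurvival = 1e-3, cultureVolume = 1e-5,
                          nReplicates = 30)
  ex <- runSelectionExperiment(cfg, SelectionProtocol(1e-8), seed = 2)
  reps <- replicateTrajectories(ex)
  expect_true(any(reps$extinct))
  expect_true(all(is.na(reps$mutant_colonies[reps$extinct])))
})

test_that("deterministic dilution remains available as an option", {
  cfg <- SimulationConfig(nReplicates = 10, dilutionMethod = "deterministic")
  ex <- runSelectionExperiment(cfg, SelectionProtocol(1e-8), seed = 8)
  expect_equal(nrow(ensembleSummary(ex)), 3)
  cfgFile <- tempfile(fileext = ".cfg")
  writeLines(c("n_replicates = 10", "dilution_method = deterministic",
               "wt_death_survival = 0.01"), cfgFile)
  rc <- readSimulationConfig(cfgFile)
  expect_identical(rc@dilutionMethod, "deterministic")
  expect_equal(rc@wtDeathSurvival, 0.01)
})

test_that("large-count binomial draws match exact moments", {
  set.seed(31)
  x <- hormevol:::.rbinomSafe(2000, 1e10, 1e-2)
  expect_lt(abs(mean(x) - 1e8), 3 * sqrt(1e10 * 1e-2 * 0.99 / 2000))
  expect_equal(sd(x) / sqrt(1e10 * 1e-2 * 0.99), 1, tolerance = 0.1)
})
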