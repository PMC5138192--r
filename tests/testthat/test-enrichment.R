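test_that("the per-step recursion reproduces the published fractions", {
  p <- SelectionProtocol(mutationRate = 1e-8)
  expect_equal(stepFraction(0, p), 4.5e-5)
  expect_equal(stepFraction(4.5e-5, p), 4.545e-3)
  expect_equal(signif(stepFraction(4.5e-5, p), 2), 4.5e-3)
  p0 <- SelectionProtocol(mutationRate = 0)
  expect_equal(stepFraction(0, p0), 0)
  expect_error(stepFraction(-0.1, p), "non-negative")
})

test_that("trajectories match the published three-step grid, caps included", {
  tr8 <- runTrajectory(SelectionProtocol(1e-8), sampleSize = 1e5)
  expect_equal(signif(rawFraction(tr8), 2), c(4.5e-5, 4.5e-3, 4.5e-1))
  expect_equal(tr8@expectedMutants[1], 4.5)  # "4-5 out of 100,000"

  tr7 <- runTrajectory(SelectionProtocol(1e-7))
  expect_gt(rawFraction(tr7)[3], 1)           # ~4.5, prints as "All"
  expect_equal(signif(rawFraction(tr7)[3], 2), 4.5)
  expect_equal(cappedFraction(tr7), pmin(rawFraction(tr7), 1))
  expect_equal(cappedFraction(tr7)[3], 1)

  tr6 <- runTrajectory(SelectionProtocol(1e-6))
  expect_equal(cappedFraction(tr6), c(4.5e-3, 4.545e-1, 1))

  # cap binds exactly at step 3 for both 1e-7 and 1e-6
  expect_true(all(rawFraction(tr7)[1:2] < 1))
  expect_true(all(rawFraction(tr6)[1:2] < 1))
})

test_that("closed form equals the recursion to 1e-12 relative tolerance", {
  for (mu in c(1e-10, 1e-8, 1e-6, 1e-4)) {
    for (E in c(1, 2, 100)) {
      p <- SelectionProtocol(mu, generationsPerStep = 45,
                             enrichmentFactor = E, nSteps = 5L)
      expect_equal(closedFormFraction(p, 1:5), rawFraction(runTrajectory(p)),
                   tolerance = 1e-12)
    }
  }
  # E = 1 degenerates to additive accumulation mu * G * k
  p1 <- SelectionProtocol(1e-8, enrichmentFactor = 1, nSteps = 4L)
  expect_equal(closedFormFraction(p1, 4), 1e-8 * 45 * 4)
  expect_error(closedFormFraction(p1, 5), "1..nSteps")
})

test_that("closed-form fractions scale linearly in mu, G and E at step 1", {
  base <- closedFormFraction(SelectionProtocol(1e-8), 1)
  expect_equal(closedFormFraction(SelectionProtocol(3e-8), 1), 3 * base)
  expect_equal(
    closedFormFraction(SelectionProtocol(1e-8, generationsPerStep = 90), 1),
    2 * base)
  expect_equal(
    closedFormFraction(SelectionProtocol(1e-8, enrichmentFactor = 500), 1),
    5 * base)
  # across steps, scaling mu by x scales every raw fraction by x
  expect_equal(closedFormFraction(SelectionProtocol(1e-7), 1:3),
               10 * closedFormFraction(SelectionProtocol(1e-8), 1:3))
})

test_that("mutation-rate inversion round-trips the closed form", {
  for (mu in 10^seq(-10, -4)) {
    p <- SelectionProtocol(mu)
    for (k in 1:3)
      # suppress the saturation warning: at large mu the raw fraction
      # exceeds 1, but the algebraic round-trip identity still holds
      expect_equal(
        suppressWarnings(invertMutationRate(closedFormFraction(p, k), k)),
        mu, tolerance = 1e-12)
  }
  expect_equal(invertMutationRate(4.5e-5, 1), 1e-8)
  expect_equal(invertMutationRate(0, 1), 0)
  expect_warning(muLow <- invertMutationRate(1.2, 3), "lower bound")
  expect_gt(muLow, 0)
})

test_that("colony detection probability follows 1 - (1 - f)^c", {
  expect_equal(detectionProbability(0, 10), 0)
  expect_equal(detectionProbability(1, 10), 1)
  expect_equal(detectionProbability(4.5e-5, 10), 4.499089e-4,
               tolerance = 1e-6)
  expect_equal(detectionProbability(0.45, 10), 0.9974670, tolerance = 1e-6)
  expect_error(detectionProbability(1.2, 10), "\\[0, 1\\]")
  # trajectory wires the capped fraction into detection
  tr <- runTrajectory(SelectionProtocol(1e-8))
  expect_equal(tr@detectionProbability,
               1 - (1 - cappedFraction(tr))^10)
})

test_that("the enrichment factor follows from the survival fractions", {
  # ~1% survival with the bile acid vs ~0.01% without
  expect_equal(enrichmentFromSurvival(1, 0.01), 100)
  expect_equal(enrichmentFromSurvival(1e-2, 1e-4), 100)
  expect_error(enrichmentFromSurvival(0, 1), "positive")
})

test_that("protocol validity rejects out-of-range parameters", {
  expect_error(SelectionProtocol(mutationRate = 1.5), "mutationRate")
  expect_error(SelectionProtocol(generationsPerStep = 0), "generationsPerStep")
  expect_error(SelectionProtocol(enrichmentFactor = 0.5), "enrichmentFactor")
  expect_error(SelectionProtocol(nSteps = 0), "nSteps")
  expect_error(SelectionProtocol(coloniesSampled = 0), "coloniesSampled")
})

test_that("protocol configs and trajectory tables round-trip through disk", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# protocol", "mutation_rate = 1e-7",
               "generations_per_step = 40", "enrichment_factor = 50",
               "n_steps = 2", "colonies_sampled = 12"), cfg)
  p <- readProtocolConfig(cfg)
  expect_equal(mutationRate(p), 1e-7)
  expect_equal(generationsPerStep(p), 40)
  expect_equal(enrichmentFactor(p), 50)
  expect_equal(nSteps(p), 2L)
  expect_equal(coloniesSampled(p), 12L)

  out <- tempfile(fileext = ".tsv")
  writeTrajectory(runTrajectory(p), out)
  tab <- utils::read.delim(out, comment.char = "#")
  expect_equal(tab$raw_fraction, rawFraction(runTrajectory(p)))
  expect_named(tab, c("step", "raw_fraction", "capped_fraction",
                      "expected_mutants", "detection_probability"))
})
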