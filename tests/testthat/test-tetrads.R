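test_that("enumeration matches brute force exactly for small k", {
  for (k in 1:3) {
    for (rule in c("any_locus_sufficient", "all_loci_required")) {
      got <- phenotypeDistribution(LocusArchitecture(k, rule))
      expect_equal(as.numeric(got), bruteForceSporeDistribution(k, rule),
                   info = sprintf("k=%d rule=%s", k, rule))
    }
  }
})

test_that("published tetrad expectations hold: 2:2 monogenic, 1/6-4/6-1/6 digenic", {
  d1 <- phenotypeDistribution(LocusArchitecture(1))
  expect_equal(as.numeric(d1), c(0, 0, 1, 0, 0))  # always 2 long : 2 short
  d1all <- phenotypeDistribution(LocusArchitecture(1, "all_loci_required"))
  expect_equal(as.numeric(d1all), c(0, 0, 1, 0, 0))

  d2 <- phenotypeDistribution(LocusArchitecture(2))
  expect_equal(attr(d2, "numerator"), c(0, 0, 6, 24, 6))
  expect_equal(attr(d2, "denominator"), 36)

  d3 <- phenotypeDistribution(LocusArchitecture(3))
  expect_equal(unname(d3["4"]), 19 / 36)
  expect_equal(attr(d3, "numerator")[5], 114)  # 114/216 = 19/36
})

test_that("P(all long) matches the inclusion-exclusion oracle exactly, k <= 8", {
  for (k in 1:8) {
    got <- phenotypeDistribution(LocusArchitecture(k))
    # exact rational check on numerators: 6^k - 4*3^k + 6
    expect_equal(attr(got, "numerator")[5], 6^k - 4 * 3^k + 6)
    expect_equal(unname(got["4"]), inclusionExclusionAllLong(k),
                 tolerance = 1e-14)
    expect_equal(sum(got), 1, tolerance = 1e-14)
    # requiring every locus makes an all-long tetrad impossible
    expect_equal(unname(
      phenotypeDistribution(LocusArchitecture(k, "all_loci_required"))["4"]),
      0)
  }
})

test_that("PD/TT/NPD classes are 1/6, 4/6, 1/6 and induce the k=2 distribution", {
  cls <- tetradClassProbabilities()
  expect_equal(sum(cls$probability), 1)
  expect_equal(cls$probability[cls$class == "PD"],
               cls$probability[cls$class == "NPD"])  # unlinked symmetry
  expect_equal(cls$probability, c(1, 4, 1) / 6)
  # induced long-spore distribution equals the enumeration
  d2 <- phenotypeDistribution(LocusArchitecture(2))
  induced <- numeric(5)
  induced[cls$long_lived_spores + 1] <- cls$probability
  expect_equal(induced, as.numeric(d2))
  expect_error(tetradClassProbabilities(LocusArchitecture(3)), "2 loci")
})

test_that("the digenic projection over six tetrads is Binomial(6, 5/6)", {
  pr <- digenicSixTetradProjection()
  expect_equal(pr$pShortPattern, 5 / 6)
  expect_equal(pr$massOn3to5, 30625 / 46656)   # = 0.65639
  expect_equal(pr$massOn3to5, sum(stats::dbinom(3:5, 6, 5 / 6)))
  expect_equal(pr$expectedCount, 5)
  expect_equal(sum(pr$distribution$probability), 1)
  # monogenic: every tetrad shows exactly two short spores
  pr1 <- digenicSixTetradProjection(arch = LocusArchitecture(1))
  expect_equal(pr1$pShortPattern, 1)
  expect_equal(pr1$distribution$probability[7], 1)  # count = 6 surely
})

test_that("all-long six-tetrad probabilities power the locus-count inference", {
  expect_equal(probAllSporesLong(6, LocusArchitecture(1)), 0)
  expect_equal(probAllSporesLong(6, LocusArchitecture(2)), (1 / 6)^6)
  expect_equal(probAllSporesLong(6, LocusArchitecture(3)), (19 / 36)^6)
  expect_equal(probAllSporesLong(6, LocusArchitecture(4)),
               (1 - 4 / 16 + 6 / 1296)^6, tolerance = 1e-12)

  res <- minConsistentLocusCount(6, alpha = 0.05)
  expect_true(all(c(1L, 2L) %in% res$excluded))  # "more than two genes"
  expect_equal(res$kMin, 4L)
  expect_equal(res$table$p_observation[2], (1 / 6)^6)

  # any alpha down to 1e-4 still excludes one and two loci
  res4 <- minConsistentLocusCount(6, alpha = 1e-4)
  expect_true(all(c(1L, 2L) %in% res4$excluded))

  # alpha -> 0 limit: the smallest k with nonzero probability, k = 2
  expect_equal(minConsistentLocusCount(6, alpha = 1e-9)$kMin, 2L)

  # per-k probability is nondecreasing under the any-locus rule
  expect_true(all(diff(res$table$p_all_long_tetrad) >= 0))

  td <- TetradDataset(matrix(TRUE, 6, 4))
  expect_equal(minConsistentLocusCount(td)$nTetrads, 6L)
  tdMixed <- TetradDataset(rbind(matrix(TRUE, 5, 4), c(TRUE, TRUE, TRUE, FALSE)))
  expect_error(minConsistentLocusCount(tdMixed), "all-long")
})

test_that("dominance classification separates the three outcomes", {
  d <- c(1, 4, 8, 12, 16, 20, 25, 30)
  short <- lawCurve(d, 12, strain = "hapWT")
  long <- lawCurve(d, 26, strain = "hapMut")
  mid <- lawCurve(d, 18, strain = "mid")
  shortDip <- lawCurve(d, 12, strain = "dipWTWT")

  domCall <- classifyDominance(short, long, shortDip,
                               lawCurve(d, 26, strain = "dipWTMut"))
  expect_identical(domCall$call, "dominant")
  expect_gte(domCall$pVsHapMut, 0.05)
  expect_lt(domCall$pVsDipWTWT, 0.05)

  recCall <- classifyDominance(short, long, shortDip,
                               lawCurve(d, 12, strain = "dipWTMut"))
  expect_identical(recCall$call, "recessive")

  midCall <- classifyDominance(short, long, shortDip, mid)
  expect_identical(midCall$call, "intermediate")

  # invariant to a uniform rescaling of the time axis
  sc <- function(cv, f) SurvivalCurve(curveDays(cv) * f, viability(cv),
                                      strain = strainName(cv))
  domScaled <- classifyDominance(sc(short, 2), sc(long, 2), sc(shortDip, 2),
                                 sc(lawCurve(d, 26), 2))
  expect_identical(domScaled$call, domCall$call)
})

test_that("tetrad datasets validate shape and round-trip through disk", {
  expect_error(TetradDataset(matrix(TRUE, 3, 3)), "4 spores")
  td <- generateTetrads(SyntheticTetradSpec(LocusArchitecture(2), 8),
                        seed = 4)
  expect_equal(nTetrads(td), 8L)
  path <- tempfile(fileext = ".tsv")
  writeTetradTable(td, path)
  td2 <- readTetradTable(path)
  expect_identical(td2@spores, td@spores)
})
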