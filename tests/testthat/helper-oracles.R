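# Independent oracles and small fixture builders used across the suite.

# Brute-force tetrad enumeration: walk every joint placement of the k loci's
# mutant-chromatid pairs over the 6 possible 2-subsets of 4 spores and tally
# the long-spore count under the rule. Feasible for k <= 4 (6^4 = 1296).
bruteForceSporeDistribution <- function(k, rule = "any_locus_sufficient") {
  pairs <- utils::combn(4, 2)
  grids <- do.call(expand.grid, rep(list(seq_len(6)), k))
  counts <- integer(5)
  for (i in seq_len(nrow(grids))) {
    hit <- matrix(FALSE, nrow = k, ncol = 4)
    for (j in seq_len(k)) hit[j, pairs[, grids[i, j]]] <- TRUE
    long <- if (rule == "any_locus_sufficient") apply(hit, 2, any)
            else apply(hit, 2, all)
    counts[sum(long) + 1L] <- counts[sum(long) + 1L] + 1L
  }
  counts / 6^k
}

# Inclusion-exclusion closed form for P(all four spores long) under the
# any-locus-sufficient rule: each spore is missed by one locus w.p. 1/2 and
# a spore pair is jointly missed w.p. 1/6 (the complementary subset).
inclusionExclusionAllLong <- function(k) 1 - 4 * (1 / 2)^k + 6 * (1 / 6)^k

# A noise-free survival curve following a given decay law on a day grid.
lawCurve <- function(days, lambda, rho = 2.5, strain = "s") {
  SurvivalCurve(days = days,
                viability = 100 * exp(-(days / lambda)^rho) /
                  exp(-(days[1] / lambda)^rho),
                strain = strain)
}

# Build the SurvivalCurve implied by the Kaplan-Meier curve of N individuals
# with the given death counts on a day grid (remaining individuals censored
# at the last day); used to cross-check the pseudo-count log-rank against
# survival::survdiff on the equivalent individual-level data.
kmCurveFromDeaths <- function(days, deaths, N, strain = "s") {
  stopifnot(length(deaths) == length(days) - 1, sum(deaths) <= N)
  atRisk <- N - cumsum(c(0, deaths))
  SurvivalCurve(days = days, viability = 100 * atRisk / N, strain = strain)
}

individualsFromDeaths <- function(days, deaths, N) {
  eventDays <- rep(days[-1], deaths)
  nCens <- N - sum(deaths)
  data.frame(time = c(eventDays, rep(days[length(days)], nCens)),
             status = c(rep(1, length(eventDays)), rep(0, nCens)))
}
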