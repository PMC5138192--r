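## Exact tetrad-segregation combinatorics for k unlinked dominant loci,
## locus-count inference from all-long tetrads, and dominance
## classification from haploid/diploid lifespan comparisons.

#' @include AllClasses.R
NULL

## The two mutant chromatids of one heterozygous locus end up in a
## uniformly random 2-subset of the 4 spores; the six possible subsets as
## bitmasks over spores 1..4.
.pairMasks <- local({
  cmb <- utils::combn(4L, 2L)
  as.integer(apply(cmb, 2, function(ix) sum(bitwShiftL(1L, ix - 1L))))
})

.popcount4 <- vapply(0:15, function(s)
  sum(bitwAnd(s, bitwShiftL(1L, 0:3)) > 0L), integer(1))

#' Exact distribution of long-lived spores per tetrad
#'
#' For k unlinked heterozygous loci, each locus places its two mutant-allele
#' chromatids on a uniformly random 2-subset of the four spores,
#' independently across loci (2:2 segregation per locus; no linkage, no
#' centromere effects). The spore phenotype follows the architecture's
#' rule: long-lived if it carries a mutant allele at any locus
#' (\code{any_locus_sufficient}) or at every locus
#' (\code{all_loci_required}). The distribution of the number of long-lived
#' spores (0..4) is computed by exact dynamic programming over the
#' \eqn{6^k} equally likely assignments; numerators and the denominator
#' \eqn{6^k} are returned as attributes, so the probabilities are exact
#' rationals represented in double precision (integers < 2^53 for k <= 10).
#'
#' @param arch A \code{\link{LocusArchitecture}}.
#' @return Named numeric vector of probabilities for 0..4 long-lived
#'   spores, with attributes \code{numerator} (integer counts) and
#'   \code{denominator} (\eqn{6^k}).
#' @examples
#' phenotypeDistribution(LocusArchitecture(1))           # point mass at 2
#' phenotypeDistribution(LocusArchitecture(2))           # 1/6, 4/6, 1/6
#' phenotypeDistribution(LocusArchitecture(3))["4"]      # 19/36
#' @export
phenotypeDistribution <- function(arch) {
  stopifnot(is(arch, "LocusArchitecture"))
  k <- arch@nLoci
  anyRule <- arch@rule == "any_locus_sufficient"
  ## DP over the running union (any-rule) or intersection (all-rule) of the
  ## k mutant-chromatid spore subsets; 16 states, exact integer counts.
  counts <- numeric(16)
  counts[(if (anyRule) 0L else 15L) + 1L] <- 1
  for (i in seq_len(k)) {
    nxt <- numeric(16)
    for (s in 0:15) {
      c0 <- counts[s + 1L]
      if (c0 == 0) next
      for (p in .pairMasks) {
        t <- if (anyRule) bitwOr(s, p) else bitwAnd(s, p)
        nxt[t + 1L] <- nxt[t + 1L] + c0
      }
    }
    counts <- nxt
  }
  num <- vapply(0:4, function(j) sum(counts[.popcount4 == j]), numeric(1))
  den <- 6^k
  structure(num / den, names = as.character(0:4),
            numerator = num, denominator = den)
}

#' Tetrad class probabilities for two unlinked loci
#'
#' For exactly two unlinked heterozygous loci the tetrads fall into the
#' classical classes parental ditype (PD), tetratype (TT) and non-parental
#' ditype (NPD) with probabilities 1/6, 4/6 and 1/6. In a backcross of a
#' double-mutant to wild type with dominant mutations under the
#' any-locus-sufficient rule, PD tetrads carry 2 long-lived spores, TT 3,
#' and NPD 4.
#'
#' @param arch A \code{\link{LocusArchitecture}} with \code{nLoci = 2}
#'   and rule \code{any_locus_sufficient} (the default for k = 2).
#' @return data.frame with columns \code{class}, \code{probability},
#'   \code{long_lived_spores}.
#' @examples
#' tetradClassProbabilities()
#' @export
tetradClassProbabilities <- function(arch = LocusArchitecture(2)) {
  stopifnot(is(arch, "LocusArchitecture"))
  if (arch@nLoci != 2L)
    stop("tetrad classes PD/NPD/TT are defined for exactly 2 loci")
  if (arch@rule != "any_locus_sufficient")
    stop("class-to-phenotype mapping assumes the any_locus_sufficient rule")
  ## Enumerate the 36 joint placements of the two loci's chromatid pairs:
  ## identical subsets -> PD, disjoint -> NPD, overlapping -> TT.
  nPD <- nNPD <- nTT <- 0L
  for (p1 in .pairMasks) for (p2 in .pairMasks) {
    if (p1 == p2) nPD <- nPD + 1L
    else if (bitwAnd(p1, p2) == 0L) nNPD <- nNPD + 1L
    else nTT <- nTT + 1L
  }
  data.frame(
    class = c("PD", "TT", "NPD"),
    probability = c(nPD, nTT, nNPD) / 36,
    long_lived_spores = c(2L, 3L, 4L)
  )
}

#' Projected tetrad pattern for a digenic trait over a small dissection
#'
#' For a digenic dominant trait (k = 2, any locus sufficient), a tetrad
#' shows one or two short-lived spores (TT or PD) with probability 5/6.
#' Over \code{nTetrads} dissected tetrads the number showing that pattern
#' is Binomial(nTetrads, 5/6). For the published dissection of six
#' tetrads, the mass on 3, 4 or 5 such tetrads — the pattern the study
#' projected for a digenic trait — is reported alongside the full
#' distribution.
#'
#' @param nTetrads Number of tetrads dissected (default 6).
#' @param arch A \code{\link{LocusArchitecture}}; the probability of the
#'   1-or-2-short pattern per tetrad is computed from its
#'   \code{\link{phenotypeDistribution}} (5/6 for the default k = 2).
#' @return A list: \code{pShortPattern} (per-tetrad probability of 1-2
#'   short spores), \code{distribution} (data.frame, counts 0..nTetrads
#'   with probabilities), \code{massOn3to5} (probability of 3, 4 or 5
#'   such tetrads), \code{expectedCount}.
#' @examples
#' digenicSixTetradProjection()$massOn3to5  # 30625/46656 = 0.6564
#' @export
digenicSixTetradProjection <- function(nTetrads = 6,
                                       arch = LocusArchitecture(2)) {
  stopifnot(is(arch, "LocusArchitecture"))
  nTetrads <- as.integer(nTetrads)
  if (is.na(nTetrads) || nTetrads < 1L) stop("nTetrads must be >= 1")
  dist <- phenotypeDistribution(arch)
  p <- unname(dist["2"] + dist["3"])  # 1 or 2 of 4 spores short-lived
  counts <- 0:nTetrads
  probs <- stats::dbinom(counts, nTetrads, p)
  list(
    pShortPattern = p,
    distribution = data.frame(tetrads_with_1or2_short = counts,
                              probability = probs),
    massOn3to5 = sum(probs[counts >= 3 & counts <= 5]),
    expectedCount = nTetrads * p
  )
}

#' Probability that every spore of every tetrad is long-lived
#'
#' Probability, under a given architecture, that all four spores of each of
#' \code{nTetrads} independently drawn tetrads are long-lived — the pattern
#' the study observed in all six dissected tetrads of each cross.
#'
#' @param nTetrads Number of tetrads (default 6).
#' @param arch A \code{\link{LocusArchitecture}}.
#' @return \code{P(4 long)^nTetrads}.
#' @examples
#' probAllSporesLong(6, LocusArchitecture(1))  # 0: monogenic is 2:2
#' probAllSporesLong(6, LocusArchitecture(2))  # (1/6)^6
#' @export
probAllSporesLong <- function(nTetrads = 6, arch = LocusArchitecture()) {
  stopifnot(is(arch, "LocusArchitecture"))
  nTetrads <- as.integer(nTetrads)
  if (is.na(nTetrads) || nTetrads < 1L) stop("nTetrads must be >= 1")
  unname(phenotypeDistribution(arch)["4"])^nTetrads
}

#' Smallest locus count consistent with an all-long tetrad observation
#'
#' Scans k = 1..\code{maxK} and reports, for each, the probability that
#' all spores of all dissected tetrads are long-lived; the smallest k whose
#' probability reaches \code{alpha} is returned as the minimal architecture
#' the observation does not reject. With six all-long tetrads under the
#' any-locus-sufficient rule, k = 1 is impossible (monogenic tetrads are
#' always 2:2) and k = 2 has probability (1/6)^6 ~ 2e-5, so any alpha
#' down to 1e-4 excludes one and two loci — the study's "more than two
#' nuclear genes" inference.
#'
#' @param observation Either a \code{\link{TetradDataset}} in which every
#'   spore is long-lived, or an integer number of all-long tetrads.
#' @param alpha Significance level (0 < alpha < 1, default 0.05).
#' @param rule Phenotype rule passed to \code{\link{LocusArchitecture}}.
#' @param maxK Largest locus count scanned (default 8, exact arithmetic).
#' @return A list: \code{table} (data.frame k, p_all_long_tetrad,
#'   p_observation), \code{kMin} (smallest consistent k, NA if none up to
#'   maxK), \code{excluded} (integer vector of rejected k).
#' @examples
#' minConsistentLocusCount(6)$kMin       # 4 at alpha = 0.05
#' minConsistentLocusCount(6, alpha = 1e-9)$kMin  # 2: smallest nonzero
#' @export
minConsistentLocusCount <- function(observation = 6, alpha = 0.05,
                                    rule = c("any_locus_sufficient",
                                             "all_loci_required"),
                                    maxK = 8L) {
  rule <- match.arg(rule)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (is(observation, "TetradDataset")) {
    if (!all(observation@spores))
      stop("observation must be the all-long pattern ",
           "(every spore long-lived)")
    n <- nTetrads(observation)
  } else {
    n <- as.integer(observation)
    if (is.na(n) || n < 1L) stop("observation must be >= 1 tetrads")
  }
  maxK <- as.integer(maxK)
  ks <- seq_len(maxK)
  pTet <- vapply(ks, function(k)
    unname(phenotypeDistribution(LocusArchitecture(k, rule))["4"]),
    numeric(1))
  pObs <- pTet^n
  kMin <- ks[pObs >= alpha][1]
  list(
    table = data.frame(k = ks, p_all_long_tetrad = pTet,
                       p_observation = pObs),
    kMin = kMin,
    excluded = ks[pObs < alpha],
    alpha = alpha, nTetrads = n, rule = rule
  )
}

#' Classify dominance from haploid and diploid lifespan curves
#'
#' A longevity trait is called dominant when the heterozygous
#' (wild-type x mutant) diploid lives essentially as long as the haploid
#' mutant parent — log-rank non-significant — while living significantly
#' longer than the wild-type x wild-type diploid; recessive when the
#' reverse holds; intermediate otherwise. This operationalizes the
#' published comparison of WT x mutant diploids against the parental
#' strains.
#'
#' @param hapWT,hapMut,dipWTWT,dipWTMut \code{\link{SurvivalCurve}}s on a
#'   common day grid: haploid wild type, haploid mutant, WT x WT diploid
#'   and WT x mutant diploid. (\code{hapWT} completes the published design
#'   and is carried in the result, but the call itself uses the mutant
#'   parent and the two diploids.)
#' @param alpha Significance level for both log-rank comparisons
#'   (default 0.05).
#' @param effectiveN Effective sample size per curve for
#'   \code{\link{logrankTest}}.
#' @return A list with \code{call} (\code{"dominant"}, \code{"recessive"}
#'   or \code{"intermediate"}), the two log-rank p-values
#'   (\code{pVsHapMut}, \code{pVsDipWTWT}), \code{alpha}, and the curves'
#'   strain labels.
#' @examples
#' d <- c(1, 5, 10, 15, 20, 30)
#' wtv <- c(100, 90, 50, 15, 4, 1); mutv <- c(100, 98, 90, 70, 45, 10)
#' cl <- classifyDominance(
#'   SurvivalCurve(d, wtv, strain = "WT"),
#'   SurvivalCurve(d, mutv, strain = "mut"),
#'   SurvivalCurve(d, wtv, strain = "WTxWT"),
#'   SurvivalCurve(d, mutv, strain = "WTxmut"))
#' cl$call
#' @export
classifyDominance <- function(hapWT, hapMut, dipWTWT, dipWTMut,
                              alpha = 0.05, effectiveN = 100) {
  for (cv in list(hapWT, hapMut, dipWTWT, dipWTMut))
    stopifnot(is(cv, "SurvivalCurve"))
  pMut <- logrankTest(dipWTMut, hapMut, effectiveN = effectiveN)$p.value
  pWT <- logrankTest(dipWTMut, dipWTWT, effectiveN = effectiveN)$p.value
  call <- if (pMut >= alpha && pWT < alpha) "dominant"
          else if (pMut < alpha && pWT >= alpha) "recessive"
          else "intermediate"
  list(call = call, pVsHapMut = pMut, pVsDipWTWT = pWT, alpha = alpha,
       strains = c(hapWT = hapWT@strain, hapMut = hapMut@strain,
                   dipWTWT = dipWTWT@strain, dipWTMut = dipWTMut@strain))
}
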