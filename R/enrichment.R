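## Deterministic serial-selection enrichment model: per-step recursion,
## closed form, mutation-rate inversion and colony-detection probability.

#' @include AllClasses.R
NULL

#' One step of the mutant-enrichment recursion
#'
#' Applies the per-step update of the long-lived-mutant fraction,
#' \deqn{f' = (f + \mu G) E,}
#' where \eqn{\mu} is the mutation rate per cell per generation, \eqn{G}
#' the generations elapsing during the growth phase and \eqn{E} the
#' enrichment factor conferred by differential death-phase survival. The
#' result is returned uncapped; fractions above 1 indicate population
#' saturation with mutants (cap with \code{pmin(., 1)}, as
#' \code{\link{runTrajectory}} does).
#'
#' @param prevFraction Mutant fraction before the step (>= 0; 0 before the
#'   first step). Vectorized.
#' @param protocol A \code{\link{SelectionProtocol}}.
#' @return The uncapped mutant fraction after the step.
#' @examples
#' p <- SelectionProtocol(mutationRate = 1e-8)
#' stepFraction(0, p)        # 4.5e-5
#' stepFraction(4.5e-5, p)   # ~4.5e-3
#' @seealso \code{\link{runTrajectory}}, \code{\link{closedFormFraction}}
#' @export
stepFraction <- function(prevFraction, protocol) {
  stopifnot(is(protocol, "SelectionProtocol"))
  if (any(is.na(prevFraction)) || any(prevFraction < 0))
    stop("prevFraction must be non-negative")
  (prevFraction +
     protocol@mutationRate * protocol@generationsPerStep) *
    protocol@enrichmentFactor
}

#' Closed form of the enrichment recursion
#'
#' The recursion \eqn{f_k = (f_{k-1} + \mu G) E} started at \eqn{f_0 = 0}
#' has the closed form
#' \deqn{f_k = \mu G E \sum_{i=0}^{k-1} E^i.}
#'
#' @param protocol A \code{\link{SelectionProtocol}}.
#' @param k Step index (vectorized), 1 <= k <= \code{nSteps(protocol)}.
#' @return The uncapped mutant fraction after step \code{k}.
#' @examples
#' closedFormFraction(SelectionProtocol(1e-8), 1:3)
#' @export
closedFormFraction <- function(protocol, k) {
  stopifnot(is(protocol, "SelectionProtocol"))
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L) || any(k > protocol@nSteps))
    stop("step index k must lie in 1..nSteps")
  E <- protocol@enrichmentFactor
  geom <- if (E == 1) k else (E^k - 1) / (E - 1)
  protocol@mutationRate * protocol@generationsPerStep * E * geom
}

#' Probability of detecting at least one mutant colony
#'
#' With a mutant fraction \eqn{f} among death-phase survivors and
#' \eqn{c} randomly picked colonies, the probability that the viability
#' panel contains at least one long-lived mutant is
#' \eqn{1 - (1 - f)^c} (binomial sampling; the with-replacement
#' approximation is exact for practical purposes because the number of
#' colonies picked is minute relative to the surviving population).
#'
#' @param fraction Mutant fraction in [0, 1] (vectorized).
#' @param colonies Number of colonies picked (>= 1).
#' @return Detection probability in [0, 1].
#' @examples
#' detectionProbability(4.5e-5, 10)  # step-1 panel almost never detects
#' detectionProbability(0.45, 10)    # step-3 panel almost always does
#' @export
detectionProbability <- function(fraction, colonies = 10) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  colonies <- as.integer(colonies)
  if (length(colonies) != 1 || is.na(colonies) || colonies < 1L)
    stop("colonies must be a single integer >= 1")
  1 - (1 - fraction)^colonies
}

#' Run the deterministic enrichment trajectory
#'
#' Applies \code{\link{stepFraction}} for each of the protocol's steps,
#' starting from a mutant fraction of 0, and records for every step the
#' raw (uncapped) fraction, the fraction capped to [0, 1] (the "All"
#' representation of a saturated population), the expected number of
#' mutants in a sample of \code{sampleSize} cells, and the probability that
#' the colony panel detects at least one mutant.
#'
#' @param protocol A \code{\link{SelectionProtocol}}.
#' @param sampleSize Sample size for the expected mutant count (default
#'   1e5, the population size the published table counts mutants in at
#'   step 1).
#' @return An \code{\link{EnrichmentTrajectory}}.
#' @examples
#' runTrajectory(SelectionProtocol(1e-8), sampleSize = 1e5)
#' @export
runTrajectory <- function(protocol, sampleSize = 1e5) {
  stopifnot(is(protocol, "SelectionProtocol"))
  if (!is.numeric(sampleSize) || length(sampleSize) != 1 || sampleSize <= 0)
    stop("sampleSize must be a single positive number")
  n <- protocol@nSteps
  raw <- numeric(n)
  f <- 0
  for (k in seq_len(n)) {
    f <- stepFraction(f, protocol)
    raw[k] <- f
  }
  capped <- pmin(raw, 1)
  .EnrichmentTrajectory(
    step = seq_len(n),
    rawFraction = raw,
    cappedFraction = capped,
    expectedMutants = capped * sampleSize,
    detectionProbability = detectionProbability(capped,
                                                protocol@coloniesSampled),
    sampleSize = as.numeric(sampleSize),
    protocol = protocol
  )
}

#' Invert the closed form to estimate the mutation rate
#'
#' Given an observed (uncapped) mutant fraction after step \code{k},
#' returns the mutation rate that the closed form
#' \eqn{f_k = \mu G E \sum_{i=0}^{k-1} E^i} implies:
#' \eqn{\hat\mu = f_k / (G E \sum_{i=0}^{k-1} E^i)}. Round-trip with
#' \code{\link{closedFormFraction}} is the identity.
#'
#' If the observed fraction is >= 1 the population was saturated and the
#' capped observation carries no information beyond a bound; a warning is
#' issued and the returned value is a lower bound on the mutation rate.
#'
#' @param observedFraction Observed mutant fraction after step \code{k}
#'   (> 0; uncapped).
#' @param k Step index at which the fraction was observed.
#' @param generationsPerStep,enrichmentFactor Protocol parameters (defaults
#'   45 and 100).
#' @return Estimated mutation rate per cell per generation.
#' @examples
#' invertMutationRate(4.5e-5, k = 1)           # 1e-8
#' invertMutationRate(closedFormFraction(SelectionProtocol(3e-9), 2), k = 2)
#' @export
invertMutationRate <- function(observedFraction, k,
                               generationsPerStep = 45,
                               enrichmentFactor = 100) {
  if (!is.numeric(observedFraction) || any(is.na(observedFraction)) ||
      any(observedFraction < 0))
    stop("observedFraction must be non-negative")
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L))
    stop("step index k must be >= 1")
  if (generationsPerStep <= 0 || enrichmentFactor < 1)
    stop("invalid protocol parameters")
  if (any(observedFraction >= 1))
    warning("observed fraction >= 1: the cap binds, ",
            "the estimate is a lower bound on the mutation rate")
  E <- enrichmentFactor
  geom <- if (E == 1) k else (E^k - 1) / (E - 1)
  observedFraction / (generationsPerStep * E * geom)
}

#' Enrichment factor from death-phase survival fractions
#'
#' The per-step enrichment factor for long-lived mutants is the ratio of
#' death-phase survival in the selective medium to survival in plain
#' medium; with the published survival of ~1\% (with the bile acid) versus
#' ~0.01\% (without), it equals 100.
#'
#' @param survivalWith Survival fraction (or percent, if both arguments use
#'   percent) in selective medium.
#' @param survivalWithout Survival fraction (or percent) in plain medium.
#' @return The dimensionless enrichment factor.
#' @examples
#' enrichmentFromSurvival(0.01, 1e-4)  # 100
#' enrichmentFromSurvival(1, 0.01)     # same, in percent
#' @export
enrichmentFromSurvival <- function(survivalWith, survivalWithout) {
  if (any(survivalWith <= 0) || any(survivalWithout <= 0))
    stop("survival fractions must be positive")
  survivalWith / survivalWithout
}
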