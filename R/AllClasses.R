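## S4 class definitions, validity methods, constructors and show() methods.

#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## SelectionProtocol
## ---------------------------------------------------------------------------

#' Parameters of the serial-selection design
#'
#' A \code{SelectionProtocol} bundles the parameters of the multi-step
#' selection of rare long-lived mutants: the per-cell per-generation mutation
#' rate towards extended longevity, the number of cell generations elapsing
#' in each growth phase, the per-step enrichment factor conferred by
#' differential death-phase survival, the number of consecutive selection
#' steps, and the number of colonies picked for viability testing after each
#' step.
#'
#' Defaults follow the published three-step lithocholic-acid selection
#' design: 45 generations per step, enrichment factor 100 (survival of ~1\%
#' of cells with the bile acid versus ~0.01\% without), 3 steps, 10 colonies
#' sampled.
#'
#' @slot mutationRate Probability of a longevity mutation per cell per
#'   generation; must lie in [0, 1) (0 is the degenerate no-mutation
#'   model, useful as a control).
#' @slot generationsPerStep Cell generations per selection step (> 0).
#' @slot enrichmentFactor Per-step fold-enrichment of long-lived mutants
#'   among death-phase survivors (>= 1).
#' @slot nSteps Number of consecutive selection steps (>= 1).
#' @slot coloniesSampled Colonies picked per viability test (>= 1).
#'
#' @param mutationRate,generationsPerStep,enrichmentFactor,nSteps,coloniesSampled
#'   See slot descriptions.
#' @return \code{SelectionProtocol()} returns a validated
#'   \code{SelectionProtocol} object.
#' @examples
#' p <- SelectionProtocol(mutationRate = 1e-8)
#' closedFormFraction(p, 1:3)
#' @aliases SelectionProtocol
#' @export SelectionProtocol
#' @exportClass SelectionProtocol
.SelectionProtocol <- setClass("SelectionProtocol",
  slots = c(
    mutationRate      = "numeric",
    generationsPerStep = "numeric",
    enrichmentFactor  = "numeric",
    nSteps            = "integer",
    coloniesSampled   = "integer"
  )
)

setValidity("SelectionProtocol", function(object) {
  msg <- character()
  if (length(object@mutationRate) != 1 || is.na(object@mutationRate) ||
      object@mutationRate < 0 || object@mutationRate >= 1)
    msg <- c(msg, "mutationRate must be a single value in [0, 1)")
  if (length(object@generationsPerStep) != 1 || object@generationsPerStep <= 0)
    msg <- c(msg, "generationsPerStep must be a single positive value")
  if (length(object@enrichmentFactor) != 1 || object@enrichmentFactor < 1)
    msg <- c(msg, "enrichmentFactor must be a single value >= 1")
  if (length(object@nSteps) != 1 || is.na(object@nSteps) || object@nSteps < 1L)
    msg <- c(msg, "nSteps must be a single integer >= 1")
  if (length(object@coloniesSampled) != 1 || is.na(object@coloniesSampled) ||
      object@coloniesSampled < 1L)
    msg <- c(msg, "coloniesSampled must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

SelectionProtocol <- function(mutationRate = 1e-8, generationsPerStep = 45,
                              enrichmentFactor = 100, nSteps = 3L,
                              coloniesSampled = 10L) {
  .SelectionProtocol(
    mutationRate = as.numeric(mutationRate),
    generationsPerStep = as.numeric(generationsPerStep),
    enrichmentFactor = as.numeric(enrichmentFactor),
    nSteps = as.integer(nSteps),
    coloniesSampled = as.integer(coloniesSampled)
  )
}

setMethod("show", "SelectionProtocol", function(object) {
  cat("SelectionProtocol\n")
  cat(sprintf("  mutation rate (mu):      %g per cell per generation\n",
              object@mutationRate))
  cat(sprintf("  generations per step (G): %g\n", object@generationsPerStep))
  cat(sprintf("  enrichment factor (E):    %g\n", object@enrichmentFactor))
  cat(sprintf("  selection steps:          %d\n", object@nSteps))
  cat(sprintf("  colonies sampled:         %d\n", object@coloniesSampled))
})

#' @rdname accessors
#' @export
setMethod("mutationRate", "SelectionProtocol", function(x) x@mutationRate)
#' @rdname accessors
#' @export
setMethod("generationsPerStep", "SelectionProtocol",
          function(x) x@generationsPerStep)
#' @rdname accessors
#' @export
setMethod("enrichmentFactor", "SelectionProtocol",
          function(x) x@enrichmentFactor)
#' @rdname accessors
#' @export
setMethod("nSteps", "SelectionProtocol", function(x) x@nSteps)
#' @rdname accessors
#' @export
setMethod("coloniesSampled", "SelectionProtocol", function(x) x@coloniesSampled)

## ---------------------------------------------------------------------------
## EnrichmentTrajectory
## ---------------------------------------------------------------------------

#' Per-step mutant-fraction trajectory of the deterministic enrichment model
#'
#' Produced by \code{\link{runTrajectory}}. Holds, for each selection step,
#' the raw (uncapped, possibly > 1) mutant fraction given by the linear
#' recursion f' = (f + mu * G) * E, the fraction capped to [0, 1] (the
#' "All" representation once the population is saturated with mutants), the
#' expected number of mutants in a stated sample, and the probability that a
#' panel of sampled colonies contains at least one mutant.
#'
#' @slot step Integer step index, 1..nSteps.
#' @slot rawFraction Uncapped per-step mutant fraction.
#' @slot cappedFraction \code{pmin(rawFraction, 1)}.
#' @slot expectedMutants \code{cappedFraction * sampleSize}.
#' @slot detectionProbability Probability that >= 1 of the sampled colonies
#'   is a mutant, \code{1 - (1 - cappedFraction)^colonies}.
#' @slot sampleSize Sample size used for \code{expectedMutants}.
#' @slot protocol The \code{\link{SelectionProtocol}} that generated the
#'   trajectory.
#' @aliases EnrichmentTrajectory
#' @exportClass EnrichmentTrajectory
.EnrichmentTrajectory <- setClass("EnrichmentTrajectory",
  slots = c(
    step                 = "integer",
    rawFraction          = "numeric",
    cappedFraction       = "numeric",
    expectedMutants      = "numeric",
    detectionProbability = "numeric",
    sampleSize           = "numeric",
    protocol             = "SelectionProtocol"
  )
)

setValidity("EnrichmentTrajectory", function(object) {
  n <- length(object@step)
  msg <- character()
  if (length(object@rawFraction) != n || length(object@cappedFraction) != n ||
      length(object@expectedMutants) != n ||
      length(object@detectionProbability) != n)
    msg <- c(msg, "all per-step vectors must have the same length")
  if (any(object@rawFraction < 0))
    msg <- c(msg, "rawFraction must be non-negative")
  if (!isTRUE(all.equal(object@cappedFraction,
                        pmin(object@rawFraction, 1))))
    msg <- c(msg, "cappedFraction must equal pmin(rawFraction, 1)")
  if (any(object@detectionProbability < 0 | object@detectionProbability > 1))
    msg <- c(msg, "detectionProbability must lie in [0, 1]")
  if (n > 1 && any(diff(object@rawFraction) <= 0))
    msg <- c(msg, "rawFraction must be strictly increasing in the step index")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnrichmentTrajectory", function(object) {
  cat(sprintf("EnrichmentTrajectory over %d selection step(s), mu = %g\n",
              length(object@step), object@protocol@mutationRate))
  print(as.data.frame(object), digits = 4)
})

#' @rdname accessors
#' @export
setMethod("rawFraction", "EnrichmentTrajectory", function(x) x@rawFraction)
#' @rdname accessors
#' @export
setMethod("cappedFraction", "EnrichmentTrajectory",
          function(x) x@cappedFraction)

#' Coerce an EnrichmentTrajectory to a data.frame
#'
#' @param x An \code{\link{EnrichmentTrajectory}}.
#' @param ... Unused.
#' @return A data.frame with columns \code{step}, \code{raw_fraction},
#'   \code{capped_fraction}, \code{expected_mutants},
#'   \code{detection_probability}.
#' @export
as.data.frame.EnrichmentTrajectory <- function(x, ...) {
  data.frame(
    step = x@step,
    raw_fraction = x@rawFraction,
    capped_fraction = x@cappedFraction,
    expected_mutants = x@expectedMutants,
    detection_probability = x@detectionProbability
  )
}

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Parameters of the stochastic selection simulator
#'
#' Culture-scale parameters for the forward simulator of the selection
#' protocol. Defaults mirror the published design: inoculation at 1e5
#' cells/ml, stationary phase at 2e8 cells/ml, death-phase survival of
#' non-mutant cells 1e-2 with the selective bile acid (1e-4 without),
#' mutants surviving 100-fold better (capped at probability 1), 100-fold
#' dilution between steps.
#'
#' @slot inoculumTiter Cells/ml at inoculation.
#' @slot stationaryTiter Cells/ml at stationary phase.
#' @slot wtDeathSurvival Probability that a non-mutant cell survives the
#'   5-week death phase in the selective (bile-acid) medium.
#' @slot wtDeathSurvivalNoLCA Same, in plain medium (used to derive the
#'   enrichment factor; the selection itself runs in selective medium).
#' @slot mutantSurvivalMultiplier Fold-increase of death-phase survival for
#'   long-lived mutants; survival probability is capped at 1.
#' @slot dilutionFactor Fold-dilution between consecutive steps (> 1).
#' @slot cultureVolume Culture volume in ml (converts titers to absolute
#'   counts; default 50 ml, a standard 250-ml Erlenmeyer flask at the
#'   protocol's 5:1 flask:medium ratio).
#' @slot nReplicates Number of replicate cultures to simulate.
#' @slot dilutionMethod \code{"binomial"} (default) subsamples cells
#'   binomially at dilution; \code{"deterministic"} divides counts and
#'   rounds. Binomial is the default because mutant counts at dilution can
#'   be O(1) and rounding a deterministic division biases the ensemble mean.
#'
#' @param inoculumTiter,stationaryTiter,wtDeathSurvival,wtDeathSurvivalNoLCA
#'   See slot descriptions.
#' @param mutantSurvivalMultiplier,dilutionFactor,cultureVolume,nReplicates
#'   See slot descriptions.
#' @param dilutionMethod \code{"binomial"} or \code{"deterministic"}.
#' @return \code{SimulationConfig()} returns a validated
#'   \code{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(nReplicates = 100)
#' @aliases SimulationConfig
#' @export SimulationConfig
#' @exportClass SimulationConfig
.SimulationConfig <- setClass("SimulationConfig",
  slots = c(
    inoculumTiter          = "numeric",
    stationaryTiter        = "numeric",
    wtDeathSurvival        = "numeric",
    wtDeathSurvivalNoLCA   = "numeric",
    mutantSurvivalMultiplier = "numeric",
    dilutionFactor         = "numeric",
    cultureVolume          = "numeric",
    nReplicates            = "integer",
    dilutionMethod         = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@inoculumTiter <= 0 ||
      object@inoculumTiter >= object@stationaryTiter)
    msg <- c(msg, "need 0 < inoculumTiter < stationaryTiter")
  for (s in c("wtDeathSurvival", "wtDeathSurvivalNoLCA")) {
    v <- slot(object, s)
    if (v <= 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in (0, 1]", s))
  }
  if (object@mutantSurvivalMultiplier < 1)
    msg <- c(msg, "mutantSurvivalMultiplier must be >= 1")
  if (object@dilutionFactor <= 1)
    msg <- c(msg, "dilutionFactor must be > 1")
  if (object@cultureVolume <= 0)
    msg <- c(msg, "cultureVolume must be positive")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (!object@dilutionMethod %in% c("binomial", "deterministic"))
    msg <- c(msg, "dilutionMethod must be 'binomial' or 'deterministic'")
  if (length(msg)) msg else TRUE
})

SimulationConfig <- function(inoculumTiter = 1e5, stationaryTiter = 2e8,
                             wtDeathSurvival = 1e-2,
                             wtDeathSurvivalNoLCA = 1e-4,
                             mutantSurvivalMultiplier = 100,
                             dilutionFactor = 100, cultureVolume = 50,
                             nReplicates = 1000L,
                             dilutionMethod = c("binomial", "deterministic")) {
  .SimulationConfig(
    inoculumTiter = as.numeric(inoculumTiter),
    stationaryTiter = as.numeric(stationaryTiter),
    wtDeathSurvival = as.numeric(wtDeathSurvival),
    wtDeathSurvivalNoLCA = as.numeric(wtDeathSurvivalNoLCA),
    mutantSurvivalMultiplier = as.numeric(mutantSurvivalMultiplier),
    dilutionFactor = as.numeric(dilutionFactor),
    cultureVolume = as.numeric(cultureVolume),
    nReplicates = as.integer(nReplicates),
    dilutionMethod = match.arg(dilutionMethod)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  titers: %g -> %g cells/ml (volume %g ml)\n",
              object@inoculumTiter, object@stationaryTiter,
              object@cultureVolume))
  cat(sprintf("  death-phase survival: wt %g (no-LCA %g), mutant x%g (capped at 1)\n",
              object@wtDeathSurvival, object@wtDeathSurvivalNoLCA,
              object@mutantSurvivalMultiplier))
  cat(sprintf("  dilution: %g-fold (%s), replicates: %d\n",
              object@dilutionFactor, object@dilutionMethod,
              object@nReplicates))
})

## ---------------------------------------------------------------------------
## PopulationState
## ---------------------------------------------------------------------------

#' Composition of a simulated culture
#'
#' Integer counts of non-mutant and long-lived-mutant cells in a culture at
#' a given point of the protocol, with the phase label tracking which
#' operation applies next.
#'
#' @slot wtCount Non-mutant cell count (integral, >= 0).
#' @slot mutantCount Mutant cell count (integral, >= 0).
#' @slot stepIndex Selection step the culture is in (0 before step 1).
#' @slot phase One of \code{"inoculated"}, \code{"stationary"},
#'   \code{"post_death"}, \code{"sampled"}.
#'
#' @param wtCount,mutantCount,stepIndex,phase See slot descriptions.
#' @return \code{PopulationState()} returns a validated
#'   \code{PopulationState}.
#' @examples
#' st <- PopulationState(wtCount = 1e5, mutantCount = 0)
#' mutantFraction(st)
#' @aliases PopulationState
#' @export PopulationState
#' @exportClass PopulationState
.PopulationState <- setClass("PopulationState",
  slots = c(
    wtCount     = "numeric",
    mutantCount = "numeric",
    stepIndex   = "integer",
    phase       = "character"
  )
)

setValidity("PopulationState", function(object) {
  msg <- character()
  if (object@wtCount < 0 || object@mutantCount < 0)
    msg <- c(msg, "cell counts must be non-negative")
  if (object@wtCount != round(object@wtCount) ||
      object@mutantCount != round(object@mutantCount))
    msg <- c(msg, "cell counts must be integral")
  if (!object@phase %in% c("inoculated", "stationary", "post_death", "sampled"))
    msg <- c(msg, "invalid phase label")
  if (length(msg)) msg else TRUE
})

PopulationState <- function(wtCount, mutantCount = 0, stepIndex = 0L,
                            phase = "inoculated") {
  .PopulationState(wtCount = as.numeric(wtCount),
                   mutantCount = as.numeric(mutantCount),
                   stepIndex = as.integer(stepIndex), phase = phase)
}

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState [step %d, %s]: wt %g, mutant %g (fraction %.3g)\n",
              object@stepIndex, object@phase, object@wtCount,
              object@mutantCount, mutantFraction(object)))
})

#' @rdname accessors
#' @export
setMethod("mutantFraction", "PopulationState", function(x) {
  tot <- x@wtCount + x@mutantCount
  if (tot == 0) return(NA_real_)
  x@mutantCount / tot
})

## ---------------------------------------------------------------------------
## SelectionExperiment (simulator output)
## ---------------------------------------------------------------------------

#' Result of a simulated selection experiment
#'
#' Returned by \code{\link{runSelectionExperiment}}. Holds the per-replicate,
#' per-step observations (counts, fractions, odds, colony draws) and the
#' ensemble summary alongside the configuration, protocol and seed used.
#'
#' @slot replicates data.frame with one row per replicate x step:
#'   \code{replicate}, \code{step}, \code{wt_count}, \code{mutant_count},
#'   \code{mutant_fraction}, \code{mutant_odds}, \code{mutant_colonies},
#'   \code{extinct}.
#' @slot summary data.frame with one row per step: ensemble means and
#'   standard errors of the mutant fraction and odds, the closed-form raw
#'   fraction, and colony-detection summaries.
#' @slot config The \code{\link{SimulationConfig}} used.
#' @slot protocol The \code{\link{SelectionProtocol}} used.
#' @slot seed Integer seed the run was started from (NA if none given).
#' @aliases SelectionExperiment
#' @exportClass SelectionExperiment
.SelectionExperiment <- setClass("SelectionExperiment",
  slots = c(
    replicates = "data.frame",
    summary    = "data.frame",
    config     = "SimulationConfig",
    protocol   = "SelectionProtocol",
    seed       = "integer"
  )
)

setMethod("show", "SelectionExperiment", function(object) {
  cat(sprintf(
    "SelectionExperiment: %d replicates x %d steps (seed %s)\n",
    object@config@nReplicates, object@protocol@nSteps,
    ifelse(is.na(object@seed), "unset", object@seed)))
  print(object@summary, digits = 4)
})

#' @rdname accessors
#' @export
setMethod("replicateTrajectories", "SelectionExperiment",
          function(x) x@replicates)
#' @rdname accessors
#' @export
setMethod("ensembleSummary", "SelectionExperiment", function(x) x@summary)

## ---------------------------------------------------------------------------
## LocusArchitecture
## ---------------------------------------------------------------------------

#' Genetic architecture of the longevity trait
#'
#' Number of unlinked nuclear loci at which the selected strain carries a
#' dominant longevity mutation, together with the rule combining loci into
#' the spore phenotype: under \code{"any_locus_sufficient"} a spore is
#' long-lived if it inherits the mutant allele at one or more loci; under
#' \code{"all_loci_required"} it must inherit the mutant allele at every
#' locus.
#'
#' @slot nLoci Number of loci, 1..10 (exact enumeration over 6^k
#'   allele-assignment patterns).
#' @slot rule \code{"any_locus_sufficient"} or \code{"all_loci_required"}.
#'
#' @param nLoci,rule See slot descriptions.
#' @return \code{LocusArchitecture()} returns a validated
#'   \code{LocusArchitecture}.
#' @examples
#' phenotypeDistribution(LocusArchitecture(2))
#' @aliases LocusArchitecture
#' @export LocusArchitecture
#' @exportClass LocusArchitecture
.LocusArchitecture <- setClass("LocusArchitecture",
  slots = c(nLoci = "integer", rule = "character")
)

setValidity("LocusArchitecture", function(object) {
  msg <- character()
  if (length(object@nLoci) != 1 || is.na(object@nLoci) ||
      object@nLoci < 1L || object@nLoci > 10L)
    msg <- c(msg, "nLoci must be a single integer in 1..10")
  if (!object@rule %in% c("any_locus_sufficient", "all_loci_required"))
    msg <- c(msg, "rule must be 'any_locus_sufficient' or 'all_loci_required'")
  if (length(msg)) msg else TRUE
})

LocusArchitecture <- function(nLoci = 1L,
                              rule = c("any_locus_sufficient",
                                       "all_loci_required")) {
  .LocusArchitecture(nLoci = as.integer(nLoci), rule = match.arg(rule))
}

setMethod("show", "LocusArchitecture", function(object) {
  cat(sprintf("LocusArchitecture: %d unlinked dominant locus/loci, rule '%s'\n",
              object@nLoci, object@rule))
})

#' @rdname accessors
#' @export
setMethod("nLoci", "LocusArchitecture", function(x) x@nLoci)
#' @rdname accessors
#' @export
setMethod("segregationRule", "LocusArchitecture", function(x) x@rule)

## ---------------------------------------------------------------------------
## TetradDataset
## ---------------------------------------------------------------------------

#' Observed spore phenotypes from dissected tetrads
#'
#' A logical matrix with one row per tetrad and exactly four columns (the
#' four ascospores of one meiosis); \code{TRUE} marks a long-lived spore.
#'
#' @slot spores Logical matrix, n x 4.
#'
#' @param spores A logical matrix/data.frame with 4 columns, or anything
#'   coercible to one.
#' @return \code{TetradDataset()} returns a validated \code{TetradDataset}.
#' @examples
#' td <- TetradDataset(matrix(TRUE, nrow = 6, ncol = 4))
#' longLivedSpores(td)
#' @aliases TetradDataset
#' @export TetradDataset
#' @exportClass TetradDataset
.TetradDataset <- setClass("TetradDataset", slots = c(spores = "matrix"))

setValidity("TetradDataset", function(object) {
  msg <- character()
  if (!is.logical(object@spores))
    msg <- c(msg, "spores must be a logical matrix")
  if (ncol(object@spores) != 4L)
    msg <- c(msg, "each tetrad must have exactly 4 spores")
  if (anyNA(object@spores))
    msg <- c(msg, "spore phenotypes must not be NA")
  if (length(msg)) msg else TRUE
})

TetradDataset <- function(spores) {
  m <- as.matrix(spores)
  if (is.character(m)) m <- m == "long"
  storage.mode(m) <- "logical"
  dimnames(m) <- list(NULL, paste0("spore", seq_len(ncol(m))))
  .TetradDataset(spores = m)
}

setMethod("show", "TetradDataset", function(object) {
  n <- nrow(object@spores)
  tab <- table(factor(rowSums(object@spores), levels = 0:4))
  cat(sprintf("TetradDataset: %d tetrad(s)\n", n))
  cat("  long-lived spores per tetrad (0..4): ",
      paste(tab, collapse = " / "), "\n")
})

#' @rdname accessors
#' @export
setMethod("nTetrads", "TetradDataset", function(x) nrow(x@spores))
#' @rdname accessors
#' @export
setMethod("longLivedSpores", "TetradDataset", function(x) rowSums(x@spores))

## ---------------------------------------------------------------------------
## SurvivalCurve and LifespanSummary
## ---------------------------------------------------------------------------

#' A chronological-lifespan survival curve
#'
#' Mean viability (percent, normalized to 100\% at the mid-log reference
#' day) across replicate cultures, with the standard error of the mean per
#' sampling day.
#'
#' @slot strain Strain label.
#' @slot days Ordered sampling days.
#' @slot viability Mean viability percent per day (normalized; in [0, 100]).
#' @slot sem Standard error of the mean per day (NA with one replicate).
#' @slot nReplicates Number of replicate cultures averaged.
#' @slot referenceDay Day whose viability defines 100\%.
#'
#' @param strain,days,viability,sem,nReplicates,referenceDay See slot
#'   descriptions.
#' @return \code{SurvivalCurve()} returns a validated \code{SurvivalCurve}.
#' @aliases SurvivalCurve
#' @export SurvivalCurve
#' @exportClass SurvivalCurve
.SurvivalCurve <- setClass("SurvivalCurve",
  slots = c(
    strain       = "character",
    days         = "numeric",
    viability    = "numeric",
    sem          = "numeric",
    nReplicates  = "integer",
    referenceDay = "numeric"
  )
)

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  n <- length(object@days)
  if (length(object@viability) != n || length(object@sem) != n)
    msg <- c(msg, "days, viability and sem must have equal length")
  if (is.unsorted(object@days, strictly = TRUE))
    msg <- c(msg, "days must be strictly increasing")
  if (any(object@viability < 0 | object@viability > 100 + 1e-8))
    msg <- c(msg, "viability percent must lie in [0, 100] after normalization")
  ref <- which(object@days == object@referenceDay)
  if (length(ref) != 1)
    msg <- c(msg, "referenceDay must be one of the sampling days")
  else if (abs(object@viability[ref] - 100) > 1e-6)
    msg <- c(msg, "viability at the reference day must be 100")
  if (length(msg)) msg else TRUE
})

SurvivalCurve <- function(days, viability, sem = rep(NA_real_, length(days)),
                          strain = "strain", nReplicates = 1L,
                          referenceDay = days[1]) {
  .SurvivalCurve(strain = as.character(strain), days = as.numeric(days),
                 viability = as.numeric(viability), sem = as.numeric(sem),
                 nReplicates = as.integer(nReplicates),
                 referenceDay = as.numeric(referenceDay))
}

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve '%s': %d day(s), %d replicate(s)\n",
              object@strain, length(object@days), object@nReplicates))
  df <- data.frame(day = object@days, mean_percent = object@viability,
                   sem = object@sem)
  print(df, digits = 4, row.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("curveDays", "SurvivalCurve", function(x) x@days)
#' @rdname accessors
#' @export
setMethod("viability", "SurvivalCurve", function(x) x@viability)
#' @rdname accessors
#' @export
setMethod("curveSEM", "SurvivalCurve", function(x) x@sem)
#' @rdname accessors
#' @export
setMethod("strainName", "SurvivalCurve", function(x) x@strain)

#' Mean and maximum chronological lifespan
#'
#' Produced by \code{\link{lifespanSummary}}. Mean CLS is the area under
#' the normalized survival curve (days); maximum CLS is the interpolated
#' day at which viability first falls below the threshold (right-censored
#' at the last sampling day when the curve never crosses it).
#'
#' @slot meanCLS Mean chronological lifespan in days.
#' @slot maxCLS Maximum chronological lifespan in days.
#' @slot maxCensored TRUE when the curve never fell below the threshold and
#'   \code{maxCLS} is the last observed day.
#' @slot threshold Viability percent defining maximum CLS (default 10).
#' @aliases LifespanSummary
#' @exportClass LifespanSummary
.LifespanSummary <- setClass("LifespanSummary",
  slots = c(meanCLS = "numeric", maxCLS = "numeric",
            maxCensored = "logical", threshold = "numeric")
)

setValidity("LifespanSummary", function(object) {
  msg <- character()
  if (object@meanCLS < 0 || object@maxCLS < 0)
    msg <- c(msg, "lifespans must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LifespanSummary", function(object) {
  cat(sprintf("LifespanSummary: mean CLS %.2f d, max CLS %.2f d%s (threshold %g%%)\n",
              object@meanCLS, object@maxCLS,
              ifelse(object@maxCensored, " (censored)", ""),
              object@threshold))
})

#' @rdname accessors
#' @export
setMethod("meanCLS", "LifespanSummary", function(x) x@meanCLS)
#' @rdname accessors
#' @export
setMethod("maxCLS", "LifespanSummary", function(x) x@maxCLS)

## ---------------------------------------------------------------------------
## Synthetic-data specs
## ---------------------------------------------------------------------------

#' Specification for synthetic viability count data
#'
#' Describes a set of strains whose true viability follows a parametric
#' decay law (Weibull by default: S(t) = exp(-(t/lambda)^rho); exponential
#' when rho = 1 via \code{law = "exponential"}), sampled on a fixed day grid
#' with plate-count (Poisson) noise on viable counts and lognormal noise on
#' hemocytometer totals.
#'
#' Defaults emulate the published assay: mid-log reference at day 1, then
#' sampling to day 40; three replicate cultures; duplicate plates totalling
#' ~120 counted colonies per measurement (dilutions adjusted per day);
#' 10\% coefficient of variation on total-cell counts; total titer 2e8
#' cells/ml. Set \code{plateCountMean = Inf} and \code{hemoCV = 0} for
#' noise-free curves.
#'
#' @slot strains data.frame with columns \code{strain}, \code{lambda}
#'   (scale, days) and \code{rho} (shape).
#' @slot days Sampling days (non-negative, strictly increasing).
#' @slot nReplicates Replicate cultures per strain.
#' @slot plateCountMean Expected colonies counted per viable-count
#'   measurement (Poisson); \code{Inf} for no plating noise.
#' @slot hemoCV Coefficient of variation of the lognormal noise on total
#'   cell counts; 0 for none.
#' @slot totalCellsPerMl True total cell concentration.
#' @slot law \code{"weibull"} or \code{"exponential"} (forces rho = 1).
#'
#' @param strains,days,nReplicates,plateCountMean,hemoCV,totalCellsPerMl,law
#'   See slot descriptions.
#' @return \code{SyntheticSurvivalSpec()} returns a validated spec.
#' @examples
#' sp <- SyntheticSurvivalSpec()
#' head(generateCounts(sp, seed = 1))
#' @aliases SyntheticSurvivalSpec
#' @export SyntheticSurvivalSpec
#' @exportClass SyntheticSurvivalSpec
.SyntheticSurvivalSpec <- setClass("SyntheticSurvivalSpec",
  slots = c(
    strains        = "data.frame",
    days           = "numeric",
    nReplicates    = "integer",
    plateCountMean = "numeric",
    hemoCV         = "numeric",
    totalCellsPerMl = "numeric",
    law            = "character"
  )
)

setValidity("SyntheticSurvivalSpec", function(object) {
  msg <- character()
  need <- c("strain", "lambda", "rho")
  if (!all(need %in% names(object@strains)))
    msg <- c(msg, "strains must have columns strain, lambda, rho")
  else {
    if (any(object@strains$lambda <= 0) || any(object@strains$rho <= 0))
      msg <- c(msg, "lambda and rho must be positive")
    if (anyDuplicated(object@strains$strain))
      msg <- c(msg, "strain labels must be unique")
  }
  if (any(object@days < 0) || is.unsorted(object@days, strictly = TRUE))
    msg <- c(msg, "days must be non-negative and strictly increasing")
  if (object@nReplicates < 1L)
    msg <- c(msg, "nReplicates must be >= 1")
  if (object@plateCountMean <= 0)
    msg <- c(msg, "plateCountMean must be positive (Inf for no noise)")
  if (object@hemoCV < 0)
    msg <- c(msg, "hemoCV must be >= 0")
  if (object@totalCellsPerMl <= 0)
    msg <- c(msg, "totalCellsPerMl must be positive")
  if (!object@law %in% c("weibull", "exponential"))
    msg <- c(msg, "law must be 'weibull' or 'exponential'")
  if (length(msg)) msg else TRUE
})

SyntheticSurvivalSpec <- function(
    strains = data.frame(strain = c("WT", "mutant"),
                         lambda = c(14, 28), rho = c(2.5, 2.5)),
    days = c(1, 2, 4, 7, 10, 14, 18, 22, 26, 30, 35, 40),
    nReplicates = 3L, plateCountMean = 120, hemoCV = 0.10,
    totalCellsPerMl = 2e8, law = c("weibull", "exponential")) {
  law <- match.arg(law)
  strains <- as.data.frame(strains)
  if (law == "exponential") strains$rho <- 1
  .SyntheticSurvivalSpec(strains = strains, days = as.numeric(days),
                         nReplicates = as.integer(nReplicates),
                         plateCountMean = as.numeric(plateCountMean),
                         hemoCV = as.numeric(hemoCV),
                         totalCellsPerMl = as.numeric(totalCellsPerMl),
                         law = law)
}

setMethod("show", "SyntheticSurvivalSpec", function(object) {
  cat(sprintf(
    "SyntheticSurvivalSpec (%s): %d strain(s), %d day(s), %d replicate(s)\n",
    object@law, nrow(object@strains), length(object@days),
    object@nReplicates))
  cat(sprintf("  plate-count mean %g, hemocytometer CV %g\n",
              object@plateCountMean, object@hemoCV))
})

#' Specification for synthetic tetrad data
#'
#' @slot architecture A \code{\link{LocusArchitecture}}.
#' @slot nTetrads Number of tetrads to draw (the study dissected 6 asci
#'   per cross).
#'
#' @param architecture,nTetrads See slot descriptions.
#' @return \code{SyntheticTetradSpec()} returns a validated spec.
#' @examples
#' generateTetrads(SyntheticTetradSpec(LocusArchitecture(1)), seed = 1)
#' @aliases SyntheticTetradSpec
#' @export SyntheticTetradSpec
#' @exportClass SyntheticTetradSpec
.SyntheticTetradSpec <- setClass("SyntheticTetradSpec",
  slots = c(architecture = "LocusArchitecture", nTetrads = "integer")
)

setValidity("SyntheticTetradSpec", function(object) {
  if (object@nTetrads < 1L) "nTetrads must be >= 1" else TRUE
})

SyntheticTetradSpec <- function(architecture = LocusArchitecture(),
                                nTetrads = 6L) {
  .SyntheticTetradSpec(architecture = architecture,
                       nTetrads = as.integer(nTetrads))
}

setMethod("show", "SyntheticTetradSpec", function(object) {
  cat(sprintf("SyntheticTetradSpec: %d tetrad(s) under k = %d ('%s')\n",
              object@nTetrads, object@architecture@nLoci,
              object@architecture@rule))
})
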