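## Seed-deterministic generators for every input the pipeline consumes,
## plus parameter-recovery checks against known ground truth.

#' @include AllClasses.R tetrads.R cls.R simulator.R
NULL

.survivalLaw <- function(t, lambda, rho) exp(-(t / lambda)^rho)

#' Generate synthetic viability count records
#'
#' Draws a count table in the exact shape the CLS pipeline reads: one row
#' per strain x replicate x day with hemocytometer totals and CFU-derived
#' viable concentrations. True viability follows the spec's decay law;
#' viable counts carry Poisson plate-count noise (expected
#' \code{plateCountMean} colonies counted per measurement, i.e. dilutions
#' are adjusted per day so plates stay countable) and totals carry
#' lognormal noise with the spec's coefficient of variation (mean
#' preserved). With \code{plateCountMean = Inf} and \code{hemoCV = 0} the
#' viability ratio equals the decay law exactly.
#'
#' @param spec A \code{\link{SyntheticSurvivalSpec}}.
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return data.frame with columns \code{strain}, \code{replicate},
#'   \code{day}, \code{total_cells_per_ml}, \code{viable_cells_per_ml}.
#' @examples
#' head(generateCounts(SyntheticSurvivalSpec(), seed = 1))
#' @export
generateCounts <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SyntheticSurvivalSpec"))
  if (!is.null(seed)) set.seed(seed)
  nd <- length(spec@days)
  sdlog <- sqrt(log(1 + spec@hemoCV^2))
  out <- list()
  for (i in seq_len(nrow(spec@strains))) {
    s <- spec@strains[i, ]
    S <- .survivalLaw(spec@days, s$lambda, s$rho)
    for (r in seq_len(spec@nReplicates)) {
      plate <- if (is.finite(spec@plateCountMean))
        stats::rpois(nd, spec@plateCountMean) / spec@plateCountMean
      else rep(1, nd)
      total <- if (spec@hemoCV > 0)
        spec@totalCellsPerMl *
          exp(stats::rnorm(nd, -sdlog^2 / 2, sdlog))
      else rep(spec@totalCellsPerMl, nd)
      out[[length(out) + 1L]] <- data.frame(
        strain = s$strain,
        replicate = paste0("rep", r),
        day = spec@days,
        total_cells_per_ml = total,
        viable_cells_per_ml = spec@totalCellsPerMl * S * plate
      )
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic tetrad phenotypes
#'
#' Draws tetrads under the spec's architecture: for each tetrad and each
#' locus, the two mutant chromatids land on a uniformly random 2-subset of
#' the four spores; spore phenotypes follow the architecture's rule. The
#' empirical spore-count distribution converges to
#' \code{\link{phenotypeDistribution}}.
#'
#' @param spec A \code{\link{SyntheticTetradSpec}}.
#' @param seed Optional integer seed.
#' @return A \code{\link{TetradDataset}}.
#' @examples
#' generateTetrads(SyntheticTetradSpec(LocusArchitecture(2), 10), seed = 1)
#' @export
generateTetrads <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SyntheticTetradSpec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec@nTetrads
  k <- spec@architecture@nLoci
  anyRule <- spec@architecture@rule == "any_locus_sufficient"
  ## n x k matrix of pair masks, combined per tetrad by OR (any) / AND (all)
  draws <- matrix(.pairMasks[sample.int(6L, n * k, replace = TRUE)],
                  nrow = n)
  combine <- if (anyRule) bitwOr else bitwAnd
  mask <- draws[, 1]
  for (j in seq_len(k)[-1]) mask <- combine(mask, draws[, j])
  spores <- sapply(0:3, function(b) bitwAnd(mask, bitwShiftL(1L, b)) > 0L)
  TetradDataset(matrix(spores, nrow = n))
}

#' Recover the mutation rate from a simulated selection experiment
#'
#' Inverts the closed-form enrichment model on the simulator's
#' ensemble-mean mutant:wild-type odds at a chosen step (the quantity the
#' linear recursion propagates exactly) and compares against the true
#' mutation rate of the protocol that drove the simulation.
#'
#' @param experiment A \code{\link{SelectionExperiment}}.
#' @param step Step whose ensemble mean is inverted (default: the last).
#' @return A list: \code{muHat}, \code{muTrue}, \code{ratio}
#'   (muHat/muTrue), \code{step}.
#' @examples
#' ex <- runSelectionExperiment(SimulationConfig(nReplicates = 200),
#'                              SelectionProtocol(), seed = 1)
#' recoverMutationRate(ex)$ratio
#' @export
recoverMutationRate <- function(experiment,
                                step = nSteps(experiment@protocol)) {
  stopifnot(is(experiment, "SelectionExperiment"))
  summ <- experiment@summary
  row <- summ[summ$step == step, ]
  if (nrow(row) != 1) stop("no such step in the experiment")
  p <- experiment@protocol
  muHat <- invertMutationRate(row$mean_odds, k = step,
                              generationsPerStep = p@generationsPerStep,
                              enrichmentFactor = p@enrichmentFactor)
  list(muHat = muHat, muTrue = p@mutationRate,
       ratio = muHat / p@mutationRate, step = step)
}

#' Frequency of the all-long six-tetrad pattern under a known architecture
#'
#' Generates many independent tetrad datasets of \code{nTetrads} each under
#' the given architecture and reports how often every spore of every tetrad
#' is long-lived, against the exact expectation
#' \code{\link{probAllSporesLong}}. For k = 3 and six tetrads the expected
#' rate is (19/36)^6, about 2 percent.
#'
#' @param arch A \code{\link{LocusArchitecture}}.
#' @param nTetrads Tetrads per dataset (default 6).
#' @param nDatasets Number of datasets (default 1e4).
#' @param seed Optional integer seed.
#' @return A list: \code{observedRate}, \code{expectedRate},
#'   \code{mcSE} (binomial Monte-Carlo standard error of the observed
#'   rate), \code{nDatasets}.
#' @examples
#' recoverLocusExclusion(LocusArchitecture(3), nDatasets = 1000, seed = 1)
#' @export
recoverLocusExclusion <- function(arch = LocusArchitecture(3), nTetrads = 6,
                                  nDatasets = 1e4, seed = NULL) {
  stopifnot(is(arch, "LocusArchitecture"))
  if (!is.null(seed)) set.seed(seed)
  nTetrads <- as.integer(nTetrads)
  nDatasets <- as.integer(nDatasets)
  ## vectorized: nDatasets x nTetrads tetrads in one sweep
  n <- nTetrads * nDatasets
  k <- arch@nLoci
  anyRule <- arch@rule == "any_locus_sufficient"
  draws <- matrix(.pairMasks[sample.int(6L, n * k, replace = TRUE)],
                  nrow = n)
  combine <- if (anyRule) bitwOr else bitwAnd
  mask <- draws[, 1]
  if (k > 1) for (j in 2:k) mask <- combine(mask, draws[, j])
  allLongTetrad <- mask == 15L
  perDataset <- matrix(allLongTetrad, nrow = nDatasets, byrow = TRUE)
  obs <- mean(apply(perDataset, 1, all))
  expd <- probAllSporesLong(nTetrads, arch)
  list(observedRate = obs, expectedRate = expd,
       mcSE = sqrt(expd * (1 - expd) / nDatasets), nDatasets = nDatasets)
}

#' Recover the lifespan ordering of synthetic strains
#'
#' Runs the generator and the CLS pipeline end to end and checks that the
#' ranking of strains by mean CLS matches the ranking by the true Weibull
#' scale parameter.
#'
#' @param spec A \code{\link{SyntheticSurvivalSpec}}.
#' @param seed Optional integer seed.
#' @param maxThreshold Threshold for maximum CLS (default 10).
#' @return A list: \code{table} (data.frame strain, lambda, mean_cls,
#'   max_cls) and \code{orderingRecovered} (logical).
#' @examples
#' recoverLifespanOrdering(SyntheticSurvivalSpec(), seed = 1)
#' @export
recoverLifespanOrdering <- function(spec = SyntheticSurvivalSpec(),
                                    seed = NULL, maxThreshold = 10) {
  stopifnot(is(spec, "SyntheticSurvivalSpec"))
  rec <- generateCounts(spec, seed = seed)
  res <- do.call(rbind, lapply(seq_len(nrow(spec@strains)), function(i) {
    s <- spec@strains[i, ]
    ls <- lifespanSummary(buildSurvivalCurve(rec, strain = s$strain),
                          maxThreshold = maxThreshold)
    data.frame(strain = s$strain, lambda = s$lambda,
               mean_cls = meanCLS(ls), max_cls = maxCLS(ls))
  }))
  list(table = res,
       orderingRecovered = identical(order(res$lambda), order(res$mean_cls)))
}
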