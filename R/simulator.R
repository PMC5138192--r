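## Stochastic forward simulator of the multi-step selection protocol:
## growth with mutation accrual, death-phase differential survival,
## dilution, and colony sampling.

#' @include AllClasses.R enrichment.R
NULL

#' Grow a culture to stationary phase
#'
#' Scales the population to the stationary titer, expanding resident
#' mutants proportionally (mutations are assumed selectively neutral during
#' growth), and adds newly arisen mutants as a Poisson draw with mean
#' \eqn{\mu G N} where \eqn{N} is the final non-mutant count. Mutation is
#' modeled during growth only; quiescent cells divide negligibly.
#'
#' @param state A \code{\link{PopulationState}} in phase
#'   \code{"inoculated"}.
#' @param config A \code{\link{SimulationConfig}}.
#' @param protocol A \code{\link{SelectionProtocol}} (supplies mu and G).
#' @return A \code{\link{PopulationState}} in phase \code{"stationary"}.
#' @examples
#' st <- PopulationState(1e5)
#' set.seed(1)
#' growToStationary(st, SimulationConfig(), SelectionProtocol())
#' @export
growToStationary <- function(state, config, protocol) {
  stopifnot(is(state, "PopulationState"), is(config, "SimulationConfig"),
            is(protocol, "SelectionProtocol"))
  if (state@phase != "inoculated")
    stop("growToStationary expects phase 'inoculated'")
  total0 <- state@wtCount + state@mutantCount
  if (total0 <= 0) stop("cannot grow an empty culture")
  N <- round(config@stationaryTiter * config@cultureVolume)
  gf <- N / total0
  mut <- round(state@mutantCount * gf)
  wt <- N - mut
  newMut <- if (wt > 0)
    stats::rpois(1, protocol@mutationRate * protocol@generationsPerStep * wt)
  else 0
  newMut <- min(newMut, wt)
  PopulationState(wtCount = wt - newMut, mutantCount = mut + newMut,
                  stepIndex = state@stepIndex, phase = "stationary")
}

#' Apply the death phase to a stationary culture
#'
#' Survival through the extended (5-week) post-quiescence death phase is a
#' single binomial draw per compartment: non-mutant cells survive with
#' probability \code{wtDeathSurvival}, long-lived mutants with probability
#' \code{min(1, wtDeathSurvival * mutantSurvivalMultiplier)}.
#'
#' @param state A \code{\link{PopulationState}} in phase
#'   \code{"stationary"}.
#' @param config A \code{\link{SimulationConfig}}.
#' @return A \code{\link{PopulationState}} in phase \code{"post_death"}.
#' @export
deathPhase <- function(state, config) {
  stopifnot(is(state, "PopulationState"), is(config, "SimulationConfig"))
  if (state@phase != "stationary")
    stop("deathPhase expects phase 'stationary'")
  pWt <- config@wtDeathSurvival
  pMut <- min(1, pWt * config@mutantSurvivalMultiplier)
  PopulationState(
    wtCount = .rbinomSafe(1, state@wtCount, pWt),
    mutantCount = .rbinomSafe(1, state@mutantCount, pMut),
    stepIndex = state@stepIndex, phase = "post_death")
}

#' Sample colonies from death-phase survivors
#'
#' Draws the number of long-lived-mutant colonies among \code{colonies}
#' randomly picked survivors, binomially at the survivor mutant fraction
#' (picked colonies are a minute fraction of survivors, so sampling with
#' replacement is an excellent approximation).
#'
#' @param state A \code{\link{PopulationState}} in phase
#'   \code{"post_death"}.
#' @param colonies Number of colonies picked (default 10).
#' @return Integer count of mutant colonies.
#' @export
sampleColonies <- function(state, colonies = 10) {
  stopifnot(is(state, "PopulationState"))
  if (state@phase != "post_death")
    stop("sampleColonies expects phase 'post_death'")
  colonies <- as.integer(colonies)
  total <- state@wtCount + state@mutantCount
  if (total < colonies)
    stop("culture effectively extinct: fewer survivors (", total,
         ") than colonies to sample (", colonies, ")")
  stats::rbinom(1, colonies, state@mutantCount / total)
}

## Binomial draws that tolerate counts beyond the integer range: exact
## rbinom up to 1e9 trials, Gaussian approximation above (relative error
## < 1e-4 at the survival probabilities used here).
.rbinomSafe <- function(n, size, prob) {
  out <- numeric(n)
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  big <- size > 1e9
  if (any(!big))
    out[!big] <- stats::rbinom(sum(!big), size[!big], prob[!big])
  if (any(big)) {
    m <- size[big] * prob[big]
    s <- sqrt(size[big] * prob[big] * (1 - prob[big]))
    out[big] <- pmin(pmax(round(stats::rnorm(sum(big), m, s)), 0), size[big])
  }
  out
}

## Internal vectorized engine: one growth/death/sample/dilute cycle for all
## replicates at once. Counts are kept as whole-number doubles.
.simulateStep <- function(wt, mut, config, protocol) {
  N <- round(config@stationaryTiter * config@cultureVolume)
  total0 <- wt + mut
  gf <- ifelse(total0 > 0, N / total0, 0)
  mutG <- round(mut * gf)
  wtG <- N - mutG
  newMut <- stats::rpois(length(wt),
    protocol@mutationRate * protocol@generationsPerStep * pmax(wtG, 0))
  newMut <- pmin(newMut, wtG)
  mutG <- mutG + newMut
  wtG <- wtG - newMut
  pWt <- config@wtDeathSurvival
  pMut <- min(1, pWt * config@mutantSurvivalMultiplier)
  wtD <- .rbinomSafe(length(wt), wtG, pWt)
  mutD <- .rbinomSafe(length(wt), mutG, pMut)
  list(wt = wtD, mut = mutD)
}

.dilute <- function(count, config) {
  p <- 1 / config@dilutionFactor
  if (config@dilutionMethod == "binomial")
    .rbinomSafe(length(count), count, p)
  else
    round(count * p)
}

#' Simulate the full multi-step selection experiment
#'
#' Runs \code{nReplicates} independent cultures through the protocol's
#' selection steps. Each step chains growth to stationary phase (with
#' Poisson mutation accrual), the death-phase differential-survival draw,
#' colony sampling from the survivors, and dilution into the next step.
#' Replicates whose surviving population falls below the colony panel size
#' are flagged extinct (their later observations are NA) rather than
#' aborting the ensemble.
#'
#' The ensemble summary reports, per step, the mean and standard error of
#' the survivor mutant fraction and of the mutant:wild-type odds, the
#' closed-form raw fraction of the deterministic model, and the
#' colony-detection rate. The linear recursion of the deterministic model
#' propagates the mutant:wild-type \emph{odds} exactly (odds multiply by E
#' under differential survival), so the odds column is the quantity to
#' compare against \code{\link{closedFormFraction}}; fraction and odds
#' coincide while the mutant fraction is small.
#'
#' @param config A \code{\link{SimulationConfig}}.
#' @param protocol A \code{\link{SelectionProtocol}}.
#' @param seed Optional integer seed for reproducibility; the same seed
#'   reproduces the experiment bit for bit.
#' @return A \code{\link{SelectionExperiment}}.
#' @examples
#' ex <- runSelectionExperiment(SimulationConfig(nReplicates = 50),
#'                              SelectionProtocol(), seed = 1)
#' ensembleSummary(ex)
#' @export
runSelectionExperiment <- function(config, protocol, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"), is(protocol, "SelectionProtocol"))
  if (!is.null(seed)) set.seed(seed)
  R <- config@nReplicates
  nStep <- protocol@nSteps
  wt <- rep(round(config@inoculumTiter * config@cultureVolume), R)
  mut <- rep(0, R)
  extinct <- rep(FALSE, R)
  rows <- vector("list", nStep)
  for (k in seq_len(nStep)) {
    stepRes <- .simulateStep(wt, mut, config, protocol)
    wtD <- stepRes$wt
    mutD <- stepRes$mut
    surv <- wtD + mutD
    extinct <- extinct | surv < protocol@coloniesSampled
    frac <- ifelse(surv > 0, mutD / surv, NA_real_)
    odds <- ifelse(wtD > 0, mutD / wtD, NA_real_)
    colonies <- rep(NA_integer_, R)
    ok <- !extinct
    colonies[ok] <- stats::rbinom(sum(ok), protocol@coloniesSampled, frac[ok])
    rows[[k]] <- data.frame(
      replicate = seq_len(R), step = k,
      wt_count = wtD, mutant_count = mutD,
      mutant_fraction = ifelse(extinct, NA_real_, frac),
      mutant_odds = ifelse(extinct, NA_real_, odds),
      mutant_colonies = colonies,
      extinct = extinct
    )
    wt <- .dilute(wtD, config)
    mut <- .dilute(mutD, config)
    wt[extinct] <- 0
    mut[extinct] <- 0
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(seq_len(nStep), function(k) {
    d <- reps[reps$step == k & !reps$extinct, ]
    n <- nrow(d)
    data.frame(
      step = k,
      n_replicates = n,
      n_extinct = sum(reps$step == k & reps$extinct),
      mean_fraction = mean(d$mutant_fraction),
      se_fraction = stats::sd(d$mutant_fraction) / sqrt(n),
      mean_odds = mean(d$mutant_odds),
      se_odds = stats::sd(d$mutant_odds) / sqrt(n),
      closed_form_raw = closedFormFraction(protocol, k),
      detection_rate = mean(d$mutant_colonies >= 1),
      mean_mutant_colonies = mean(d$mutant_colonies)
    )
  }))
  .SelectionExperiment(replicates = reps, summary = summ, config = config,
                       protocol = protocol,
                       seed = if (is.null(seed)) NA_integer_
                              else as.integer(seed))
}
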