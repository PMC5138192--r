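---
title: "Modeling hormetic selection for yeast longevity: enrichment dynamics, tetrad segregation, and chronological lifespan"
author: "hormevol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hormetic selection for yeast longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormevol)
```

# The experimental system

Exogenous lithocholic acid (LCA), a bile acid that yeast cannot synthesize,
extends the chronological lifespan (CLS) of quiescent *S. cerevisiae* cells
through a hormetic stress response. This makes it a selective agent: in a
culture held for weeks past stationary phase, cells carrying spontaneous
longevity mutations outlive their siblings, and LCA widens that survival gap.
A serial-selection design exploits this — grow a culture to stationary phase
(~45 generations from a 1×10^5 cells/ml inoculum to 2×10^8 cells/ml), hold it
through a 5-week death phase in which ~1% of cells survive with LCA versus
~0.01% without, dilute 100-fold, and repeat. `hormevol` implements the
quantitative backbone of such an experiment: the deterministic enrichment
model, a stochastic simulator of the protocol, the tetrad-segregation
combinatorics used to count the loci behind a selected trait, CLS survival
analysis, and synthetic-data generators with known ground truth.

# The deterministic enrichment model

Let $f_k$ be the fraction of long-lived mutants after selection step $k$,
$\mu$ the per-cell per-generation rate of longevity mutations, $G$ the
generations per growth phase, and $E$ the enrichment factor. Each step adds
newly arisen mutants and multiplies the mutant fraction by $E$:

$$f_k = (f_{k-1} + \mu G)\,E, \qquad f_0 = 0,$$

with closed form $f_k = \mu G E \sum_{i=0}^{k-1} E^i$. The enrichment factor
is the ratio of death-phase survival probabilities, here
$10^{-2}/10^{-4} = 10^2$. With $\mu = 10^{-8}$, $G = 45$ and $E = 100$ the
model yields fractions $4.5\times10^{-5}$, $\approx4.5\times10^{-3}$ and
$\approx4.5\times10^{-1}$ over three steps:

```{r}
runTrajectory(SelectionProtocol(mutationRate = 1e-8), sampleSize = 1e5)
```

Two reading conventions matter. First, the recursion is linear, so $f_k$ can
exceed 1; values $\ge 1$ mean the population is saturated with mutants and
are reported capped ("All" in the printed table) alongside the raw value,
which preserves the algebra (`runTable1Report()` emits both). Second, the
recursion propagates, exactly, the mutant:wild-type *odds* rather than the
fraction: under differential survival the odds multiply by $E$ while the
realized fraction is $fE/(1 + f(E-1))$. The distinction is invisible while
$f \ll 1$ but matters at step 3, and it determines which simulator statistic
the model should be compared against (below).

Inverting the closed form estimates the mutation rate from an observed
enrichment level: $\hat\mu = f_k / (G E \sum_{i<k} E^i)$
(`invertMutationRate()`). If the observed fraction is capped the estimate is
only a lower bound, and the function warns. Finally, the chance that a panel
of $c$ picked colonies contains at least one mutant is
$1 - (1-f)^c$ (`detectionProbability()`); at step 1
($f = 4.5\times10^{-5}$, $c = 10$) this is $4.5\times10^{-4}$, which is why
a 10-colony screen finds nothing after one step, while by step 3 detection
is near-certain.

$G$ deserves a note: the published design states ~45 generations per step,
although $\log_2(2\times10^8/10^5) \approx 11$ doublings separate the
titers; the excess presumably reflects turnover during growth. $G$ is
therefore a free protocol parameter defaulting to 45, and every quantity
downstream scales linearly in it.

# The stochastic simulator

`runSelectionExperiment()` propagates integer cell counts through each step:

* **Growth.** The population scales to the stationary titer; resident
  mutants expand proportionally (no growth cost or benefit is modeled — the
  selected mutants show no growth-rate difference), and new mutants arise as
  a Poisson draw with mean $\mu G N$, attributing mutation to the growth
  phase only, since quiescent cells divide negligibly.
* **Death phase.** The 5-week death phase collapses to one binomial draw per
  compartment: wild-type survival $p$, mutant survival
  $\min(1, p \times \text{multiplier})$. Only endpoint survival is
  specified by the protocol, so a day-by-day hazard would add parameters
  without adding constraint. Note that at the default $p = 10^{-2}$ and
  multiplier 100 the mutant survival probability sits exactly at the cap.
* **Colony sampling.** Mutant colonies among 10 picks are binomial at the
  survivor mutant fraction; replicates with fewer survivors than the panel
  are flagged extinct rather than aborting the ensemble.
* **Dilution.** Default is binomial subsampling at rate 1/dilution. A
  deterministic division (`dilutionMethod = "deterministic"`) is available,
  but it is not the default because mutant counts at dilution are small
  (thousands of cells in a 50-ml culture, fewer in smaller ones) and
  rounding a division injects deterministic bias into the ensemble mean.

Counts use exact `rbinom()` draws up to 10^9 trials and a Gaussian
approximation above (relative error < 10^-4 at these survival
probabilities); the default 50-ml culture volume — a 250-ml Erlenmeyer flask
at the protocol's 5:1 flask-to-medium ratio — pushes wild-type draws to
10^10 trials. Volume matters scientifically, not just numerically: the
100-fold dilution bottlenecks the absolute number of mutant cells carried
between steps, and an unphysically small culture (say 1 ml) would reduce the
~4,500 step-1 mutants of a 50-ml culture to a Poisson mean below 1, wildly
dispersing the replicate trajectories.

The ensemble summary reports both the mutant fraction and the mutant odds
with Monte-Carlo standard errors. As derived above, the closed form is the
odds; the package's agreement checks therefore compare ensemble-mean odds to
`closedFormFraction()` at every step, which coincides with comparing
fractions at steps 1–2 where $f \ll 1$:

```{r}
ex <- runSelectionExperiment(SimulationConfig(nReplicates = 300),
                             SelectionProtocol(1e-8), seed = 1)
ensembleSummary(ex)[, c("step", "mean_fraction", "mean_odds",
                        "se_odds", "closed_form_raw", "detection_rate")]
```

# Tetrad segregation and locus counting

After backcrossing a selected haploid mutant to wild type and sporulating
the diploid, each heterozygous locus segregates 2:2 among the four spores of
a tetrad. For $k$ unlinked loci, each locus's two mutant chromatids land on
a uniformly random 2-subset of the four spores, independently across loci —
$6^k$ equally likely placements, which `phenotypeDistribution()` enumerates
exactly by dynamic programming over spore subsets, returning integer
numerators over $6^k$ (doubles hold these exactly for $k \le 10$).

The phenotype rule is a genuine modeling choice the experiment does not pin
down: whether one mutant locus suffices for extended CLS, or all are
required. The default is `any_locus_sufficient`, the only rule compatible
with the published digenic projection (tetrads with 3 long-lived spores are
impossible under `all_loci_required`, which never yields more than 2); the
alternative rule is implemented and exposed.

Key exact results, each cross-checked in the test suite against brute-force
enumeration and the inclusion–exclusion identity
$P(\text{all 4 long}) = 1 - 4(1/2)^k + 6(1/6)^k$:

* $k=1$: every tetrad is 2:2 — a point mass at 2 long spores.
* $k=2$: 2, 3 or 4 long spores with probabilities 1/6, 4/6, 1/6 — the
  classical PD : TT : NPD = 1 : 4 : 1 expectation for unlinked loci
  (`tetradClassProbabilities()`). A tetrad shows "one or two short spores"
  with probability 5/6, so over six dissected tetrads the count of such
  tetrads is Binomial(6, 5/6): mass $\approx 0.656$ on {3, 4, 5}, mean 5
  (`digenicSixTetradProjection()`).
* $k=3$: $P(\text{all 4 long}) = 19/36$.

Observing *all four spores long-lived in all six tetrads* therefore has
probability 0 under $k=1$ and $(1/6)^6 \approx 2\times10^{-5}$ under $k=2$ —
excluded at any $\alpha \ge 10^{-4}$ — which is the "more than two nuclear
genes" inference. `minConsistentLocusCount()` reports the full per-$k$
table rather than a single verdict, because under these assumptions $k=3$
is also improbable ($ (19/36)^6 \approx 0.022$): at $\alpha = 0.05$ the
smallest consistent count is 4. The published claim stops at "more than
two"; the table leaves the $k=3$ judgment to the reader. Loci are assumed
unlinked with no centromere linkage (no map positions are available), so
the tetratype frequency is not reduced.

```{r}
minConsistentLocusCount(6, alpha = 0.05)$table
```

Dominance is classified from survival curves
(`classifyDominance()`): the trait is dominant when the heterozygous
WT×mutant diploid is log-rank-indistinguishable from the haploid mutant
parent *and* significantly longer-lived than the WT×WT diploid, at the same
$\alpha = 0.05$; "lives almost as long" is operationalized as a
non-significant log-rank, matching how the published comparisons are
annotated.

# CLS survival analysis

Viability percent is $100 \times \text{viable}/\text{total}$ from CFU and
hemocytometer counts, normalized per replicate to 100% at the mid-log
reference day; curves are replicate means ± SEM
(`buildSurvivalCurve()`). Normalized values marginally above 100% are
counting noise and are clamped silently — they occur in essentially every
real dataset — with a warning reserved for exceedances beyond 110%, which
suggest a unit mix-up.

Neither "mean" nor "maximum" CLS has a universal definition; the package
states its own: **mean CLS** is the area under the normalized survival
fraction versus time (trapezoidal, counting viability as 100% from
inoculation to the reference day), and **maximum CLS** is the linearly
interpolated time at which viability first falls below a threshold,
default 10%, right-censored at the last sampling day when never crossed.
Both are configurable in `lifespanSummary()`.

## The curve-based log-rank test

CLS data are fraction-valued curves, not individual death times, so the
standard log-rank machinery needs a bridge: `logrankTest()` converts each
curve into a pseudo-cohort of `effectiveN` individuals. The normalized
survival fraction is projected onto a non-increasing sequence by
pool-adjacent-violators (the maximum-likelihood monotone fit, which lets
transient up-wiggles cancel instead of counting as deaths), rounded to
at-risk counts, and differenced into per-day death counts, with survivors
censored at the last day; the usual $\sum(O-E)$ and hypergeometric variance
sums then give a 1-df chi-square. Identical curves give a statistic of
exactly 0 and $p = 1$; the construction reproduces `survival::survdiff`
exactly when the curves are themselves Kaplan–Meier curves of `effectiveN`
individuals (a test asserts this equivalence).

`effectiveN` is the single most consequential parameter: it states how much
sampling information a curve is credited with, and p-values move
monotonically with it. The default is 100 per curve. This value is
*calibrated jointly with the synthetic noise model*: under the generator's
defaults (below), the null rejection rate of the test at $\alpha = 0.05$
sits at its nominal level (slightly conservative, ~0.04 over thousands of
null curve pairs — the acceptance suite checks 0.05 ± 0.02). Users applying
the test to data with very different replicate counts or plating depths
should expect the nominal level to hold only approximately and can adjust
`effectiveN` accordingly.

Group means (e.g. mean CLS across replicate cultures) are compared with an
unpaired two-tailed Welch t-test (`tTestUnpaired()`, a thin wrapper over
`stats::t.test`); Welch rather than pooled because nothing licenses an
equal-variance assumption. Zero-variance edge cases follow the convention
$p = 1$ for equal means, $p = 0$ otherwise.

# The synthetic-data generator

`generateCounts()` emulates the CLS assay. True viability follows a Weibull
decay $S(t) = e^{-(t/\lambda)^\rho}$ — chosen because CLS curves are
sigmoidal in time; it is a stand-in, not a claim about yeast mortality, and
an exponential law is available. Defaults, chosen once for realism:

| parameter | default | rationale |
|---|---|---|
| $\lambda$ (scale) | 14 d (WT), 28 d (mutant) | WT CLS on 0.2% glucose declines over 2–5 weeks; selected mutants roughly double it |
| $\rho$ (shape) | 2.5 | sigmoidal decline |
| sampling days | 1, 2, 4, 7, 10, 14, 18, 22, 26, 30, 35, 40 | mid-log reference day 1, denser early, ~weekly late |
| replicates | 3 | the published survival panels use n = 3 |
| plate-count mean | 120 colonies | duplicate plates of ~60, mid 30–300 countable range; dilutions adjusted per day |
| hemocytometer CV | 10% | typical chamber-count variability |
| total titer | 2×10^8 /ml | stationary-phase titer |

Viable counts carry Poisson noise at the plate-count mean (constant
*relative* noise, because dilution is adjusted to keep plates countable at
any viability); totals carry mean-preserving lognormal noise. The
plate-count default of 120 is the calibration partner of
`effectiveN = 100` discussed above. Setting `plateCountMean = Inf` and
`hemoCV = 0` recovers the decay law exactly, which parameter-recovery tests
use.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: biological replicate-to-replicate variation
beyond counting noise (real cultures drift in $\lambda$ itself),
non-monotone artifacts such as regrowth of survivors, day-to-day batch
effects shared across strains, and any dependence between strains assayed
together. Tetrad generation (`generateTetrads()`) draws from the exact
segregation model, so it shares that model's idealizations: no linkage, no
gene conversion, complete spore viability.

`recoverMutationRate()`, `recoverLocusExclusion()` and
`recoverLifespanOrdering()` close the loop: simulate with known truth, run
the matching pipeline stage, compare. At the default problem sizes the
mutation rate is recovered well within a factor of 1.5, the all-long
six-tetrad pattern under $k=3$ appears at the exact $(19/36)^6 \approx 2\%$
rate within Monte-Carlo error, and noise-free lifespan ordering is exact.

# Numerical choices and degenerate inputs

* Tetrad probabilities are exact integer ratios (numerators carried as
  attributes); no floating-point enumeration error up to $k = 10$.
* Closed form vs recursion agree to a relative 10^-12 (tested).
* $\mu = 0$ is allowed as a degenerate no-mutation control.
* Saturated observations (fraction ≥ 1) invert to a lower bound with a
  warning, never silently.
* Curves must share day grids for testing; mismatched grids are an error,
  not an interpolation.
* A curve with no pseudo-deaths (flat at 100%) makes the log-rank variance
  zero; this is reported as a degenerate-input error.
* All generators and the simulator are seed-deterministic;
  `runFullDemo()` derives per-stage seeds from one global seed
  (`deriveSeed()`), so stages rerun standalone bit-identically.

# Problem sizes

The shipped checks run the simulator at 10^3 replicates (seconds — the
engine is vectorized across replicates), tetrad sampling at 10^4 datasets,
and log-rank calibration over 10^3 synthetic curve pairs; these sizes put
Monte-Carlo standard errors well below the tolerances being asserted while
keeping a full run comfortably under a minute.

# Known limitations

* $E$ is a single lever: LCA dose–response (5/50/250 µM), repeated dosing,
  and any fitness cost of the mutations are out of scope.
* The death phase is an endpoint draw; time-resolved death-phase dynamics
  are not modeled.
* Whether non-mutant survivors of a step survived by chance or by LCA
  protection is not distinguishable in this design; the wild-type survival
  probability absorbs both.
* The locus-count inference conditions on the observed all-long pattern and
  the stated segregation model; epigenetic or mitochondrial inheritance
  would violate its premises and are not modeled.
* The log-rank calibration is specific to the default noise model and
  `effectiveN`; it is a documented pairing, not a theorem.
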