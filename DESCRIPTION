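Package: hormevol
Title: Hormetic Selection Dynamics, Tetrad Segregation and Chronological
    Lifespan Analysis in Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for experimental evolution of yeast
    longevity under hormetic selection by exogenous bile acids. Implements
    the deterministic serial-selection enrichment model for rare long-lived
    mutants (per-step recursion, closed form, mutation-rate inversion and
    colony-sampling detection probabilities), a stochastic forward simulator
    of the three-step selection protocol (growth, mutation accrual,
    differential death-phase survival, dilution, colony sampling), exact
    tetrad-segregation combinatorics for k unlinked dominant loci with
    locus-count inference and dominance classification, chronological
    lifespan (CLS) survival analysis from colony-count data including a
    curve-based log-rank test, and seed-deterministic synthetic-data
    generators with parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cls.R'
    'enrichment.R'
    'hormevol-package.R'
    'io.R'
    'simulator.R'
    'tetrads.R'
    'synthetic.R'
    'pipeline.R'
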