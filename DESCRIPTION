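Package: wfgrid
Title: Forward-Time Wright-Fisher Simulation on Population Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A forward-time Wright-Fisher population-genetic simulator on a
    rectangular grid of populations. Each generation passes through ordered
    phases of stochastic extinction, binomial migration between adjacent (or
    arbitrarily connected) cells, infinite-sites Poisson mutation with fixed
    or gamma-distributed selection coefficients, logistic growth with an
    optional Allee effect, and fitness-weighted Wright-Fisher reproduction.
    Selection and demography can vary in space (per grid cell) and in time
    (scheduled events, or chained runs through lossless checkpoints). The
    package computes allele frequencies, expected heterozygosity and Fst
    together with their classical closed-form expectations, and exports
    genotypes in GENEPOP, PLINK (.ped/.map) and Geneland text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
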