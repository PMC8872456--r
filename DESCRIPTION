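Package: divflow
Title: Population-Genetic Analysis of Divergence with Gene Flow from
    Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multilocus microsatellite surveys of
    recently diverged, host-associated taxa exchanging genes. Provides
    GENEPOP and long-format genotype input/output, allele-frequency and
    inbreeding-coefficient (F_IS) estimation, rarefied allelic richness
    with asymptotic-model fits, private-allele detection, Jost's D_EST and
    Nei's (1972) genetic distance with neighbor-joining population
    networks and bootstrap-over-loci supports, a per-locus principal
    component analysis of latitudinal clines with projection of derived
    taxa onto ancestral axes, a likelihood classifier for migrant, F1 and
    backcross genotypes, and a two-island migration-selection equilibrium
    model that estimates the selection coefficients required to maintain
    observed allele-frequency differences between sympatric population
    pairs under symmetric gene flow. Includes a Wright-Fisher two-deme
    simulator with stepwise microsatellite mutation used for calibration
    and testing, and a pipeline that assembles all analyses into tabular
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
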