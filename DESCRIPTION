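Package: ldscape
Title: Linkage Disequilibrium Decay, Persistence of Phase, and Local LD Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing linkage disequilibrium (LD) in phased
    multi-population SNP panels. Computes haplotype-based signed r and
    r-squared for marker pairs, genome-wide binned LD decay curves,
    and persistence of LD phase between populations under two
    common-marker scenarios. Implements a sliding-window local LD map
    in which the decay model E(r^2) = 1/(1 + alpha*d) is fitted as a
    Gamma generalized linear model with inverse link and fixed unit
    intercept, per window and per chromosome, and transformed into
    per-position expected-r2 tracks. Includes sample and marker quality
    control (call rate, minor allele frequency, exact Hardy-Weinberg
    test, pedigree-based pruning of parents and full sibs) and a
    founder-mosaic / Wright-Fisher haplotype simulator for generating
    panels with controllable LD decay and between-population
    divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    rlang,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
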