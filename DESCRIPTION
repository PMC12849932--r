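Package: reciprsa
Title: Behavioral and Neural Pattern Analyses of Reciprocal Partner Choice
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing reciprocal partner choice between altruistic
    and strategic benefactors under varying reciprocal efficiency. Implements
    the behavioral stage (two-factor scoring of subjective ratings, per-condition
    mixed-effects choice regressions yielding the relative weight of Communal
    Concern, Relative Self-payoff comparisons, Greenhouse-Geisser corrected
    repeated-measures ANOVA, linear-trend contrasts, Mann-Whitney tests), a
    cross-study neural pattern-expression stage (dot-product expression of
    condition maps against communal/obligation weight maps, min-max
    normalization, neural relative weight, within-participant permutation
    tests), and a parcel-wise representational similarity stage (four cognitive
    dissimilarity models, correlation-distance neural RDMs, mixed-effects RDM
    regression, Benjamini-Hochberg FDR, striatal ROI mode). A synthetic-data
    generator plants known behavioral and neural structure so every stage is
    verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
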