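Package: gamerge
Title: Genetic-Algorithm Selection of Isomorphous Merging Groups for
    Multi-Crystal SAD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions large pools of partial crystallographic sub-data
    sets (small-wedge, serial or mesh collections) into isomorphous
    merging groups that maximize weak anomalous signal.  Provides a
    complete unmerged-reflection merging-statistics engine (R_merge,
    R_meas, mean I/sigma, CC1/2, CC_anom, SigAno, completeness,
    multiplicity, per resolution shell and overall), a genetic algorithm
    over group-label chromosomes with weighted fitness and automatic
    weight balancing, an append-only archive of every evaluated grouping,
    a random-selection control, an exhaustive oracle for small pools, a
    synthetic multi-crystal data generator with planted non-isomorphous
    classes and known anomalous differences, and archive post-analysis
    relating merging statistics to anomalous-signal recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
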