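Package: pugmark
Title: Footprint Identification Technique for Individual and Sex
    Classification of Pumas
Version: 0.1.0
Authors@R:
    person("WildTrack", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Landmark-based morphometric identification of pumas (Puma
    concolor) from left-hind footprints. Converts 25 landmark points per
    footprint into 128 variables (lengths, angles, areas), classifies
    pairs of footprint trails as same or different individual with a
    stepwise-selected canonical discriminant analysis stabilised by a
    reference centroid group and a confidence-ellipse overlap rule,
    estimates the number of individuals by Ward clustering of pairwise
    trail distances cut at a tuned threshold, and classifies sex with a
    stepwise linear discriminant. Includes a hierarchical synthetic
    footprint generator, sequential holdback validation, jackknife sex
    validation, readers for TPS/JSON landmark files and measurement
    tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    readxl,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
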