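Package: inmtools
Title: Elastic-Network Instantaneous Normal Mode Analysis of Hinge-Protein
    Conformational Switching
Version: 0.1.0
Authors@R:
    person("inmtools", "developers", email = "inmtools@example.org",
           role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for detecting open/closed
    conformational switching in two-lobe (hinge) proteins such as the
    AMPK/SNF1 kinase domain. Builds Tirion elastic networks from structure
    snapshots, computes instantaneous normal modes (INM), scores each
    snapshot against open and closed reference templates with a
    frequency-weighted mode-overlap similarity, classifies states and counts
    transitions, and computes Schlitter quasi-harmonic configurational
    entropy by region, Shrake-Rupley solvent accessible surface area
    profiles, and backbone dihedral statistics. Includes a synthetic
    hinge-protein generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
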