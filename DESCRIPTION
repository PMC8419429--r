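Package: dosetra
Title: Dosage-QTL Mapping of Wood Anatomy Traits in Irradiation Hybrid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide dosage quantitative trait locus (dQTL) scans for
    clonally replicated irradiation-hybrid pedigrees carrying large insertions
    and deletions. Segments the genome into bins at indel breakpoints, scores
    relative gene dosage (RDS) per line and bin, tests dosage-trait association
    with tie-corrected Kendall tau-b, and controls family-wise error with a
    modified Bonferroni correction based on the effective number of independent
    bins from hierarchical clustering of bin-bin dosage correlations.
    Also provides wood vessel morphometrics from segmented cross-section
    tables (equivalent-circle diameter, vessel frequency, circularity,
    grouping index, non-lumen fraction), allometric height correction of
    traits by log-log residuals, broad-sense heritability as clonal
    repeatability, and a calibrated synthetic population generator for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
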