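Package: cistromeHet
Title: Cistrome Heterogeneity Analysis Across Patient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor binding-site
    heterogeneity across a patient cohort. Builds a cross-cohort site
    universe from per-patient ChIP-seq peak sets, ranks and bins sites by
    prevalence (shared / partially shared / unique), computes enrichment
    statistics along the ranking (hypergeometric bin enrichment,
    observed-over-expected mutation rates with Fisher's exact test,
    permutation tests of density equality), links enhancers to genes
    through chromatin-loop anchors, fits per-gene Gaussian GLMs of
    expression on enhancer occupancy scores with permutation
    likelihood-ratio p-values, partitions copy-number events into
    gene-exclusive and enhancer-exclusive classes, and classifies patients
    by good/poor-outcome site ratios. Includes a synthetic-cohort
    generator with known ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
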