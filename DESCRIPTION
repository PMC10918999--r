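Package: proteotypeR
Title: Two-Stage Taxonomic Proteotyping and Functional Profiling of
    Metaproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for taxonomic proteotyping of complex microbiome samples
    from peptide-spectrum identifications. Builds a peptide-to-taxon index by
    in-silico tryptic digestion of reference proteomes, attributes identified
    spectra to taxa at seven taxonomic ranks (Taxon-to-Spectrum Matches),
    runs a two-round genus-then-species cascade, estimates per-taxon protein
    biomass from spectral counts or precursor intensities, assembles a
    customized sample-specific protein sequence database, and profiles
    function through KEGG-orthology pathway coverage and abundance
    weighting. A synthetic-community simulator with recorded ground truth
    makes every stage testable without mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
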