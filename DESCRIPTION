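Package: sugarcat
Title: Genomic Reconstruction of Bacterial Sugar Utilization Machinery
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative-genomics reconstruction of carbohydrate
    utilization pathways in bacterial genome panels. Implements family-based
    homology scanning with Smith-Waterman local alignment, bidirectional
    best-hit orthology, chromosomal gene-cluster (operon) detection and
    phyletic co-occurrence profiling, regulon inference by iterative
    position-weight-matrix motif discovery with a minimum-training-score
    threshold and a cross-genome conservation filter, all-components pathway
    presence calling with pseudogene-aware impairment states, and
    predicted-versus-observed growth-phenotype concordance scoring. Ships a
    seeded synthetic genome generator (planted homolog families, operons,
    transcription-factor binding sites, mosaic pathway presence and
    pseudogene lesions) with machine-readable ground truth, and packaged
    reference tables for a 19-genome Shewanella-style sugar catabolome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
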