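Package: lantivar
Title: Characterization of Nisin-Like Lanthipeptide Variants and Their Gene
    Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the in-silico characterization of nisin-like
    lanthipeptide variants. Reconstructs mature core peptides from
    reference-numbered edit lists, derives and names variant differences
    from global protein alignments, computes percent-identity matrices and
    neighbour-joining dendrograms, and predicts peptide masses under the
    lanthipeptide dehydration model. Models nisin-type biosynthetic gene
    clusters as ordered labelled genes, compares cluster layouts by gene
    adjacencies, scans nucleotide sequence for nisin-associated promoter
    consensus elements, TCT-N8-TCT direct repeats, and Rho-independent
    terminators under a nearest-neighbour hairpin energy model, and screens
    whole genomes for nisin-cluster gene content via ORF calling and
    protein homology. Includes a seeded synthetic-data generator that
    plants peptide variants, gene clusters, regulatory features, and whole
    pangenomes with truth manifests for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
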