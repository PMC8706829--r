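Package: mitocompare
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of fungi: parsing annotated
    circular mitochondrial genomes from GenBank flat files, nucleotide
    composition and genic/intergenic region accounting, classification of
    circular gene-order rearrangement patterns across many taxa, gene-junction
    interval typing (overlap/abutting/spacer states), positional naming of
    group I introns by homologous insertion site, detection of intronic and
    intergenic open reading frames, intraspecific variation tallies from
    banded high-identity alignments with synonymous/nonsynonymous calls under
    the mold mitochondrial genetic code, and maximum-likelihood marginal
    ancestral-state reconstruction of discrete mitogenomic characters on
    rooted phylogenies under the Mk model. A synthetic-data generator produces
    fully annotated circular mitogenomes, mutated individuals, and
    tree-evolved characters with known ground truth so every analysis stage
    can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    ape,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
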