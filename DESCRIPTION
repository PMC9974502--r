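Package: karyevo
Title: Ancestral Karyotype Reconstruction from Ohnolog Macrosynteny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing vertebrate ancestral karyotypes from
    chromosome-scale ortholog tables. Assigns homologous chromosomes between an
    outgroup (amphioxus-like) genome and a post-2R-duplication ingroup genome by
    relative ortholog abundance, extracts ohnolog groups retained from the two
    rounds of vertebrate whole-genome duplication, infers chromosome fusion
    events and places them into epochs (pre-1R, post-1R, post-2R, lineage
    branches) by a parsimony sharing rule, and reconstructs per-node chromosome
    counts on a fixed chordate/vertebrate tree. Includes a forward genome
    evolution simulator (fusions, two WGD rounds, asymmetric gene loss,
    translocation noise) that emits the same table formats with full ground
    truth, and small chromosome-level statistics: tau expression breadth,
    interchromosomal Hi-C contact enrichment, relative ChIP levels of repeats,
    and amplicon expression normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
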