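Package: consanno
Title: Consensus Gene Annotation from Multiple Evidence Sources via Orthology
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines protein-coding gene predictions from multiple structural
    annotation sources (ab initio, transcriptome- or homology-derived GFF3
    files) into a single consensus annotation. Each source annotation is
    treated as a pseudo-species in an orthology inference over a user-supplied
    species tree; hierarchical orthologous groups (HOGs) at the node ancestral
    to the sources define the candidate consensus gene repertoire. Genes
    supported by at least two sources, or by one source plus an ortholog in an
    outgroup species, are retained; the representative model is the one with
    the longest coding sequence (or from the highest-priority source), with
    all of its isoforms. Includes a simplified built-in orthology engine
    (Smith-Waterman + reciprocal best hits + tree-guided grouping), orthoXML
    import for interoperability with external orthology tools, GffCompare-style
    sensitivity/precision evaluation at the exon, locus and transcript levels,
    and a synthetic genome-annotation simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
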