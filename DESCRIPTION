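Package: pangrna
Title: Minimum Guide RNA Sets for Multiple Targets in Multiple Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs CRISPR guide RNA (gRNA) panels that cover homologous
    target genes across many genome assemblies. Homologues of reference
    genes are discovered in non-reference assemblies by seeded local
    alignment, candidate spacers are enumerated under a flexible PAM
    mini-language (3' or 5' PAM, IUPAC ambiguity codes, alternation,
    PAM-less), candidates are filtered by GC content, by positional
    off-target thresholds evaluated against background genomes, and by
    membership in annotated features inferred through alignment lift-over,
    and a set-cover solver emits the smallest possible (optionally
    mutually exclusive) gRNA sets covering every target. A deterministic
    synthetic pangenome generator supports fully hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
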