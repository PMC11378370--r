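Package: genebirth
Title: Reconstructing How De Novo Protein-Coding Genes Originate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the evolutionary scenario by which de novo protein-coding
    genes arise from non-genic DNA in a yeast-like clade. Each catalogued gene
    is assigned a birth edge on a rooted species tree by parsimony, ancestral
    sequences at both ends of that edge are reconstructed by marginal maximum
    likelihood on a progressive multiple alignment of glocally mapped
    orthologous regions, and the evolution from the non-genic ancestor to the
    genic descendant is summarised as GC content, mutation-class frequencies,
    open-reading-frame length changes under three start-codon rules, and
    Kozak-signature turnover, with intergenic ORFs as the neutral background.
    Includes a sequence-evolution simulator with a complete ground-truth event
    log so the whole pipeline is testable without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
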