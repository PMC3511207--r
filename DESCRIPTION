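Package: irdkit
Title: Annotation and Diversity Analysis of Pin-II Proteinase Inhibitor
    Repeat Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Pin-II type serine proteinase inhibitor
    precursors of the kind found in Capsicum annuum (CanPIs). Decomposes
    precursor amino-acid sequences into a 25-residue signal peptide, tandem
    ~50-residue inhibitory repeat domains (IRDs) carrying an 8-cysteine
    scaffold and a C-[P/T]-P1-X-C reactive site, and inter-domain linkers;
    classifies each domain as trypsin- or chymotrypsin-inhibitory from its P1
    residue; deduplicates domains and signal peptides into catalogs; computes
    clone-library abundance statistics across induction treatments; predicts
    average masses of proteolytically processed single-domain peptides and
    assigns MALDI peaks; builds UPGMA dendrograms from pairwise p-distances;
    and simulates synthetic precursor libraries with ground truth so every
    stage can be benchmarked.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    GenomicRanges,
    IRanges,
    rtracklayer
Config/testthat/edition: 3
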