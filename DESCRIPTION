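Package: metagpa
Title: Case-Control Metagenomic Genome-Phenome Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a genome-phenome association workflow for
    case/control metagenomic sequencing experiments. Contigs are scored
    for phenotype enrichment from per-contig RPKM ratios between a
    phenotype-selected (case) and a total (control) library, protein
    domain families are tested for association with the enriched contig
    set by a two-sided Fisher exact test with Bonferroni correction, and
    candidates are refined by residue-level differential conservation
    scoring of group-labelled protein alignments (BLOSUM80), exact
    hypergeometric domain co-occurrence analysis, neighborhood summaries,
    and clade-purity scoring on phylogenetic trees. A seeded synthetic
    fixture generator produces complete case/control datasets with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
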