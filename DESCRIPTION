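Package: trgscout
Title: Detection of De Novo Born Taxonomically Restricted Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conservative pipeline for identifying high-confidence
    taxonomically restricted gene families (TRGFs) in a clade of annotated
    genomes and for inferring whether each family was born de novo from
    previously noncoding sequence. Implements cross-species homology family
    construction with a length-tolerance rule, protein screening against
    outgroup proteomes, nucleotide-level discovery and multiple alignment of
    homologous genomic regions, detection of conserved open reading frames in
    outgroups, codified annotation quality control, synteny context checks,
    an intron length modulo-3 test, and conserved-stop-codon frame analysis.
    Ships a synthetic clade simulator that evolves annotated genomes down a
    species tree with substitutions and indels and plants de novo births,
    diverged duplicates, pseudogenizations and gene losses with a ground-truth
    ledger, so every pipeline stage can be benchmarked without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
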