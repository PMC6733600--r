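Package: toxscreen
Title: Suppressor-Mutation Enrichment Analysis for Lethal-Selection Amplicon Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of saturation-mutagenesis suppressor screens
    on toxin-antitoxin amplicons sequenced with overlapping paired-end reads.
    Provides a synthetic clone-pool simulator (PCR mutagenesis with transition
    bias and rare single-base indels, lethal selection against a planted
    suppressor set, read-level sequencing error), quality trimming and
    filtering, quality-aware merging of overlapping read pairs, global affine
    alignment with edit-structure classification of reads into zero,
    single-substitution, single-indel and multi classes, positional and
    nucleotide-specific count matrices across replicates, a replicate-aware
    negative-binomial Wald test with dispersion shrinkage and
    Benjamini-Hochberg FDR control, TMM-normalised sample clustering, and
    annotation utilities (per-region mutation densities, minimal functional
    motifs, codon positions, RNA base-pair covariation classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    edgeR,
    MASS,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
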