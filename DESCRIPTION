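Package: lncpalm
Title: Long Noncoding RNA Discovery, Classification, Target Prediction and
    SNP Association for Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide long noncoding RNA (lncRNA)
    analysis in plants, modelled on oil palm studies. Candidate transcripts
    are screened with length, exon-count, abundance and open-reading-frame
    filters, classified into lincRNA, natural antisense (NAT), intronic and
    sense classes (with six NAT geometry subtypes), and merged into loci.
    Target genes are predicted in cis (overlap or 2-kb flanking window) and
    in trans (nearest-neighbour RNA duplex energy), lncRNA/target pairs are
    screened for Pearson coexpression against a significance-derived
    threshold, and SNPs inside lncRNA loci are tested for trait association
    with a Q+K mixed linear model (population covariates plus kinship).
    A synthetic-data module generates annotation, genomes, expression,
    genotypes and phenotypes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
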