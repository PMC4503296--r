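Package: smchap
Title: Joint Haplotype Assembly and Genotype Calling by Deterministic
    Sequential Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles single-individual haplotypes from base-space
    sequencing fragments while jointly re-calling genotypes at
    heterozygous SNP sites.  Reads are arranged in a fragment matrix over
    the nucleotide alphabet (plus a gap symbol) and the two haplotypes
    are reconstructed one SNP site at a time by a deterministic
    sequential Monte Carlo (particle filtering) recursion that
    exhaustively scores every heterozygous extension of the partial
    haplotype pair, propagates phase information across the gaps of
    paired-end reads, and keeps the top-K weighted particles.  Includes
    allele masking of rare (likely erroneous) bases, splitting of the
    fragment matrix into independently assemblable blocks, bidirectional
    assembly with likelihood/MEC-based reconciliation, a calibrated
    fragment simulator, and evaluation metrics (MEC score, reconstruction
    rate, switch error rate, genotype-repair rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
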