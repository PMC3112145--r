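Package: palinarm
Title: Molecular Evolution of Genomic Palindromes and Duplicated Gene Clusters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the evolutionary study of large genomic
    palindromes (inverted repeats) and the gene families that live on them.
    Detects inverted and direct repeats by k-mer seeded self-comparison,
    profiles arm-to-arm nucleotide divergence in non-overlapping windows and
    calls conversion-resistant divergent islands, detects gene-conversion
    tracts with Sawyer's fragment statistic and permutation significance,
    estimates synonymous and nonsynonymous divergence by the Nei-Gojobori
    pathway method with optional CpG-codon masking, builds neighbor-joining
    phylogenies with bootstrap support, compares exon-phase profiles across
    gene models, and dates duplicate divergence by substitution-count
    scaling. Synthetic-sequence generators with full ground-truth records
    make every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
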