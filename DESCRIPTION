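Package: patrilineR
Title: Y-Chromosome Patriline Analysis with SNP, CNV and Allele-Specific
    CNV Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-layer analysis of male-specific Y-chromosome markers for
    patrilineal studies: multi-locus SNP haplotypes, integer copy-number
    calls for loci on repeated fragments derived from qPCR Ct triplicates
    against a two-copy autosomal reference, and allele-specific copy-number
    splits inferred from pyrosequencing allele ratios at double-base-call
    sites. Provides haplotype and nucleotide diversity statistics with
    standard errors, UPGMA dendrograms, median-joining haplotype networks
    with maximum-parsimony pruning, a hierarchical (SNP to CNV to AS-CNV)
    line refinement with a layered distance, and a seeded synthetic-data
    generator with truth files for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
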