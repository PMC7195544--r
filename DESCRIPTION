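Package: gbsphylo
Title: Genotyping-by-Sequencing SNP Discovery, Filtering and Phylogenetic
    Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing Genotyping-by-Sequencing (GBS) data for
    phylogenetics. Converts barcoded short restriction-site reads into
    candidate SNPs by two routes, reference-free pairing of 64-bp tags at
    Hamming distance one and ungapped unique-best mapping against a reference
    genome, then calls diploid genotypes under a binomial likelihood model
    with Phred-scaled genotype quality. A composable suite of matrix filters
    (sample and site missingness, minor allele frequency, heterozygosity,
    depth floors and ceilings, invariant-site removal, physical linkage
    pruning) supports threshold sweeps that track both SNP counts and
    downstream tree stability. Neighbor-joining with site-resampling bootstrap
    and Robinson-Foulds bipartition comparison quantify topology concordance
    across assemblies and filter settings, and a fully seeded read simulator
    with known truth (species tree, genotypes, reference) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
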