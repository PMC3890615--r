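Package: homeolyze
Title: Homoeolog Expression Partitioning and Bias Analysis for Allopolyploid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing homoeologous gene expression in allopolyploids
    from RNA-seq alignments against a single diploid reference. Reads are
    partitioned into subgenome classes by diagnostic homoeo-SNPs, quantified as
    RPKM with mixture-model presence calling, and compared with a negative
    binomial conditional exact test. Downstream summaries cover homoeolog
    expression bias and its conservation across accessions, twelve-category
    expression-level-dominance classification, diploid-versus-polyploid
    cross-classifications, and neighbor-joining expression phylogenies. A
    synthetic-data module generates complete studies (reference, annotation,
    SNP index, alignments, and negative binomial count tables) with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    phangorn,
    jsonlite
Config/testthat/edition: 3
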