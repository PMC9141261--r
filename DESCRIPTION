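Package: snpkit
Title: SNP-Array Diversity and Functional-Allele Analysis for Rice Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diploid SNP-array genotypes of inbred crop
    germplasm collections, motivated by highland rice breeding panels.
    Provides validated readers and writers for genotype matrices, marker
    maps, sample metadata and functional-gene catalogs; per-marker quality
    statistics with a four-threshold filter (GenTrain, missing rate,
    heterozygosity, minor allele frequency) and inter-marker gap and density
    summaries; pairwise polymorphic-SNP-ratio distances with a
    neighbor-joining tree builder, Newick export and tree-cut grouping;
    graphical-genotyping style segmentation of chromosomes into homozygous
    and heterozygous fragments with per-sample heterozygosity profiles;
    favorable-allele calling for cataloged genes by causal-SNP or haplotype
    comparison with cohort frequency reports; and a seeded generator of
    synthetic collections with planted group structure, wild-accession
    heterozygosity and exact favorable-allele carrier counts for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
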