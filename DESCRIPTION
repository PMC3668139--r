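Package: eqtlWeights
Title: eQTL-Weighted Multiple Testing for Genome-Wide Association Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Incorporates expression quantitative trait locus (eQTL)
    information into genome-wide association studies through weighted
    multiple-testing procedures. Builds general (eQTL p-value based) and
    binary (two-valued) per-SNP weights normalized to mean one, applies
    weighted Bonferroni, Holm and Benjamini-Hochberg corrections with an
    optional effective number of independent tests, tests eQTL enrichment
    of SNP sets by exact hypergeometric tails, estimates pairwise linkage
    disequilibrium (r-squared and D-prime) from unphased genotypes by an
    EM algorithm, prunes SNPs in sliding windows, extends SNP sets with
    LD proxies, screens weighted hit lists for LD-novel associations, runs
    per-SNP logistic association scans with genotype quality control, and
    validates family-wise error rate control by phenotype permutation on
    simulated case-control genotype data with LD blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, MultipleComparison, SNP,
    GeneExpression, LinkageDisequilibrium, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
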