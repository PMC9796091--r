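Package: triovc
Title: Direct and Indirect Parental Genetic Effects in Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of offspring phenotypes that depend
    directly on the offspring's own genotypes and indirectly on maternal and
    paternal genotypes. Implements genomic-relatedness-matrix (GRM) based
    maximum-likelihood estimation over parent-offspring trios with four nested
    model specifications, nested model comparison (AIC, likelihood-ratio
    tests), and gene-environment-correlation decomposition, together with
    genotype quality control, relatedness pruning, subscale scoring of ordinal
    item ratings, and a synthetic trio genotype/phenotype generator so the
    whole pipeline is testable without restricted cohort data. Includes
    readers and writers for PLINK bed/bim/fam and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
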