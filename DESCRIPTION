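Package: famqls
Title: Family-Based Rare-Variant Association with Kinship-Aware Score Tests
    and Gene Collapsing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Case-control association testing of rare variants in pedigree
    data. Implements quasi-likelihood score tests (MQLS and WQLS) that model
    the genotype covariance among relatives through the kinship matrix,
    together with gene-level collapsing of rare variants into a dichotomous
    carrier indicator so that signals from different private mutations in the
    same gene can be combined across families. Includes a gene-drop simulator
    (pedigree construction, Mendelian transmission of rare alleles, liability
    threshold phenotypes with replicate phenotype sets), power estimation over
    phenotype replicates, and descriptive summaries of how rare variants
    distribute and transmit within families. Readers and writers for
    LINKAGE/PLINK pedigree and genotype text formats and plain TSV tables are
    provided, with tibble-first interfaces, broom-style tidiers and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
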