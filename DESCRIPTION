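Package: metconcord
Title: Concordance of Somatic Mutations, miRNA Expression and Protein
    Pathways Between Primary Tumours and Matched Metastases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for comparing paired primary and metastatic tumour
    samples across three molecular levels. Scores intra-tumour
    heterogeneity of somatic mutations from mutant allele frequency and
    tumour cellularity, classifies clonality backgrounds (subclonal,
    clonal, copy-number variation, wild type) and summarises
    primary-metastasis discordance with a one-proportion z-test.
    Quantifies miRNA expression by the delta-delta-Ct method with
    tumour-cellularity normalisation, categorises relative ratios and
    measures paired concordance with Cohen's kappa and
    Benjamini-Hochberg-adjusted proportion tests. Calls protein
    alterations from reverse-phase protein array intensities using a
    population standard-deviation cutoff and a hierarchical
    pathway/pair/population 50 percent rule. Ships the printed study
    tables as plain-text fixtures and a seeded synthetic-cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
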