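Package: f1loh
Title: Copy-Neutral LOH, Mutant-Allele Duplication and Clonal Dynamics in
    F1-Hybrid Tumor Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tumor/normal genomic inference for F1-hybrid mouse leukemias.
    Computes B-allele-frequency and depth-of-coverage log-ratio tracks at
    strain-informative SNPs, segments and classifies them into retained
    heterozygosity, copy-neutral loss of heterozygosity (uniparental
    disomy), hemizygous deletion and gain, and calls mutant-allele
    duplication events. Compares variant allele frequencies between paired
    primary and relapsed tumors with exact tests to label mutations as
    enriched, depleted, de novo, or lost, and groups them into clones.
    Summarises mutation burden per megabase and per-pathway recurrence
    across a cohort. Includes a synthetic F1-exome read-count generator
    with known purity, copy-number events, and clonal structure, so the
    whole pipeline runs and can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
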