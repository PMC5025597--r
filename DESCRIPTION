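Package: apobecsig
Title: APOBEC3 Mutational-Signature Enrichment and Association Analysis in Breast Cancer Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-sample APOBEC3 mutational-signature fold-enrichment scoring
    from somatic SNV catalogs (TCW/WGA trinucleotide motifs in +/-20-nt
    context windows), exact-test significance with Benjamini-Hochberg
    correction and APOBEC high/low classification; label-permutation
    association of gene alterations (SNV, amplification, loss) with
    APOBEC-high status, cohort-wide and per PAM50 subtype; subtype
    association by chi-square with pairwise post hoc tests; segmental
    copy-number breakpoint comparison by Mann-Whitney U test; and a
    deterministic synthetic-cohort generator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
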