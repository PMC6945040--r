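Package: mendelsieve
Title: Family-Based Recessive Variant Prioritization with Synthetic Pedigree Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate causal variants in a nuclear family under an
    autosomal recessive model: subtraction of a background variant catalog to
    retain family-private sites, depth and genotype-missingness quality
    filtering, Mendelian segregation filtering (homozygous alternate in
    affected offspring, heterozygous carrier parents, no homozygous alternate
    unaffected sibling), and a simplified coding-impact triage with HGVS-style
    frameshift consequence prediction and truncation arithmetic. Includes qPCR
    delta-Ct normalization for candidate-gene expression checks and a fully
    synthetic pedigree data generator (annotated toy genome, background catalog,
    Mendelian genotype transmission, one planted recessive coding insertion with
    truth files) so the whole cascade is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
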