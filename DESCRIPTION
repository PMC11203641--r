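Package: bulkseg
Title: Bulked-Segregant Variant Filtering and Candidate Mutation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate causal mutations from two phenotype-selected
    sequencing bulks of a segregating population. Implements record-level VCF
    filtering with allele-balance, depth and quality-by-depth thresholds,
    effect-class restriction to missense and frameshift annotations, bulk
    subtraction of shared variants, exact binomial consistency scoring of
    per-bulk SNP indices against Mendelian expectations, candidate ranking,
    and IGV batch-script emission for visual review. Also provides the
    accompanying downstream analyses: chi-square segregation tests,
    marker-phenotype cosegregation checks, haplotype classification of
    cultivar panels, coding-sequence deletion effects, spectrophotometric
    chlorophyll and carotenoid quantification, and delta-delta-Ct relative
    expression. A forward simulator of selfed and F2 crosses, pooled read
    depths, and annotated bulk VCFs makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
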