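Package: stimqtl
Title: Stimulus-Response QTL Mapping, Enhancer Priming and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for context-specific gene-regulation
    analysis in paired stimulation designs: paired differential calling of
    stimulus-responsive accessibility peaks and genes, cis caQTL/eQTL mapping
    with hierarchical (eigenMT or permutation based) multiple-testing
    correction and secondary-signal discovery, genotype-by-condition
    response-QTL testing with a donor random intercept, LD-based enhancer
    priming classification, motif and interval-overlap enrichment statistics,
    and GWAS-QTL colocalization via approximate conditional analysis and
    single-causal-variant colocalization posterior probabilities. Includes a
    negative-binomial paired-design simulator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    IRanges,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    lme4,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
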