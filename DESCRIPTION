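Package: pleioscan
Title: Cross-Trait Polygenic Pleiotropy and Causality from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying shared polygenic architecture between a complex
    disease and a panel of molecular traits (for example blood proteins) using
    only GWAS summary statistics. Implements LD score regression heritability
    and genetic correlation with liability-scale conversion, conditional
    (block-LD) imputation of missing association Z scores, P-value-informed LD
    clumping, genome-wide Z-score correlation tests with effective-test FDR
    correction, gene-based association with binomial pleiotropy enrichment and
    weighted Stouffer combination, four-model regional colocalization
    posteriors over LD-independent loci, and a latent-causal-variable estimator
    of the genetic causality proportion. A block-LD summary-statistic simulator
    with known heritability, genetic correlation and causal topology supports
    end-to-end testing without access to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
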