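Package: vmrqtl
Title: Variably Methylated Regions, methQTL Scanning, and
    Gene-Environment Model Competition for Neonatal Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects variably methylated regions (VMRs) in Infinium-style
    beta-value matrices using median-absolute-deviation scores, scans every
    VMR representative CpG against all heterologous SNPs to find the best
    methQTL pair with a P-value-distribution skew diagnostic and
    cis/trans/disrupting classification, competes genotype, environment and
    gene-by-environment linear models by AIC with Akaike deltas and adjusted
    R-squared confidence filtering, runs genotype-segregated environment
    regressions with Bonferroni correction, and tests probe lists for
    CpG-island shore/shelf context enrichment by one-tailed hypergeometric
    test. A synthetic cohort generator with planted genetic, environmental
    and interaction effects (Balding-Nichols population structure, logit
    scale effects) makes every stage verifiable without access to cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
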