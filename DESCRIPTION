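Package: flockgwas
Title: Read-Depth Variant Calling and Multi-Model Association Analysis for
    Sheep Blood-Trait Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit reproducing the computational stages of
    a sheep red-blood-cell trait association study: windowed read-depth
    scanning with run-rule calling of duplications and deletion/alternate
    (divergent, non-mapping) regions; genotype and sample quality control with
    an exact Hardy-Weinberg test; a four-model (additive, genotypic 2-df,
    dominant, recessive) linear-regression association scan with covariates,
    best-model selection, significance tiers and conditional re-analysis;
    EM haplotype-frequency estimation of two-locus linkage disequilibrium
    (D, D-prime, r-squared); and production-trait contrasts from a linear
    mixed model with a sire-within-breed random effect and Tukey-Kramer
    adjusted pairwise genotype comparisons. A synthetic-data module generates
    depth panels, LD-structured genotypes and phenotypes with the statistical
    structure the analysis assumes, so the full pipeline runs end-to-end with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
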