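Package: glyrare
Title: Score-Based Rare-Variant and Haplotype Meta-Analysis for Glycaemic Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cohort-level score statistics and meta-analysis machinery for
    exome-chip style rare-variant association studies of glycaemic traits.
    Implements single-variant score tests with minor-allele-count filters,
    gene-based SKAT and Madsen-Browning weighted-sum burden tests from
    summed score statistics, conditional analysis by covariance projection,
    leave-one-variant-out SKAT scans, exact binomial direction-consistency
    tests, and a family-aware haplotype association model (EM expected
    dosages plus a linear mixed model with a family random intercept) whose
    cohort-level fits are combined by multivariate fixed-effects
    meta-analysis that tolerates cohort-specific haplotype sets. A synthetic
    multi-cohort generator reproduces the rare-variant architecture these
    methods assume, so the full pipeline runs end-to-end without access to
    individual-level consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
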