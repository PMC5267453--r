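Package: MethylPurity
Title: Tumor Purity Estimation and Purity-Aware Differential Methylation
    from DNA Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates tumor purity from Illumina 450k-style DNA
    methylation beta values using informative differentially methylated
    CpG sites (iDMCs) and kernel-density mode estimation, and performs
    purity-aware differential methylation analysis. Differential
    methylation between tumor and normal samples is tested with a
    heteroscedastic linear model in which purity enters as a
    multiplicative design factor, with geometric-mean variance shrinkage
    and a Wald test. When normal controls are unavailable, differentially
    methylated CpGs are detected from tumor samples alone by regressing
    methylation on purity and ranking sites by the posterior probability
    that the effect size exceeds a threshold. A synthetic-data generator
    produces beta matrices with known purities and known differential
    methylation truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
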