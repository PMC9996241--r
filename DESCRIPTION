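Package: sigact
Title: Kinase and Transcription Factor Activity Inference for Multiomics Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers kinase activities from phosphoproteomic log2 fold-changes by a
    one-sample z-test over substrate sites and transcription factor activities by
    signed regulon enrichment of mRNA fold-changes; associates activities with
    somatic mutations and with each other by study-adjusted linear models;
    benchmarks substrate priors with balanced-resampling AUROC; classifies
    tumour-versus-perturbation kinase specificity; links activities to overall
    survival with Kaplan-Meier/log-rank and Cox proportional-hazards models; and
    stratifies samples by activity profiles with hierarchical clustering.
    Ships a synthetic multiomics cohort generator with planted kinase/TF activity
    shifts, mutation effects and survival hazards for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
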