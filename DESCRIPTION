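Package: episcan
Title: Individual-Specific DNA Methylation Outlier Screening for 450K Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting individual-specific DNA methylation
    outliers (epimutations) in Illumina HumanMethylation450 cohort data:
    beta-value computation from signal intensities, probe-level quality
    filters, empirical-Bayes location/scale batch correction, per-probe
    Wilcoxon group testing with Benjamini-Hochberg control, a per-probe
    Smirnov-Grubbs single-outlier scan with Bonferroni family-wise control,
    SNP-probe filtering, CpG-island and gene-feature annotation with
    promoter-proximal and clustered/isolated classification, per-subject
    epimutation burden summaries with Tukey multiple comparisons, generic
    hypergeometric gene-set enrichment, and a synthetic 450K cohort
    generator with ground-truth injections for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
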