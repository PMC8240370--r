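Package: methylSex
Title: Sex and Sex-Chromosome Karyotype Classification from DNA Methylation
    Beta Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts sample sex and detects sex chromosome aneuploidies
    (45,XO and 47,XXY) from Illumina methylation array beta values alone, so
    that it works on text-format GEO uploads that lack raw IDAT files.
    Implements the full pipeline: beta computation from methylated and
    unmethylated signal intensities, sample-level missingness QC, probe-mean
    imputation, per-sample autosomal Z-score normalization, pooled-variance
    t-test selection of sex-associated CpG probes with Bonferroni correction,
    two principal-component axes fitted separately to ChrX and ChrY probes,
    and quadrant-based karyotype calling. Includes a synthetic methylation
    cohort generator with ground-truth karyotypes for end-to-end testing
    without external downloads, a human-readable trained-model format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
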