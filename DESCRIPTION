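Package: tincaller
Title: Tumour-in-Normal Aware Somatic Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Somatic single-nucleotide variant calling for tumour/normal
    pairs in which the matched normal sample is itself contaminated by
    tumour cells (tumour-in-normal, TiN), as is common in haematological
    malignancies where purified T cells or buccal swabs still carry the
    malignant clone. Implements a genotype-pair likelihood model in which
    both samples carry their own aberrant cell fraction, a profile-likelihood
    estimator of the TiN level, germline log-odds (GLOD) rescue of indels
    flagged as present in the matched normal, copy-number-corrected cancer
    cell fraction utilities for longitudinal clone tracking, and a synthetic
    pileup simulator that benchmarks variant recovery across TiN levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
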