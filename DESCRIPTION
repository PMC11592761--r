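Package: secondhit
Title: Germline Screening and Somatic Second-Hit Detection for Paired
    Tumor-Normal Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based triage of germline variants in hereditary-cancer
    gene panels and integrated somatic second-hit detection from matched
    tumor multi-omics (small variants, structural variants, copy
    number/LOH segments, expression outliers, promoter methylation),
    with tumor mutational burden, cohort-level summary statistics, and a
    fully synthetic paired-cohort simulator with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
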