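Package: bescan
Title: Base-Editor Amenability Scanning for Pathogenic Transcript Variants
Version: 0.1.0
Authors@R:
    person("bescan", "developers", email = "bescan@example.org", role = c("aut", "cre"))
Description: Decides which pathogenic single-nucleotide variants of a gene are
    correctable by DNA base editors (adenine, cytosine and glycosylase base
    editors) and which Cas proteins provide a usable PAM and editing-window
    placement. Parses HGVS c. variant descriptions, harmonizes clinical
    significance across two database-export dialects, calls mutational
    consequence from a transcript model, classifies transition/transversion
    and required editor class, enumerates protospacer placements with
    bystander-edit reporting for a configurable Cas library, and summarizes
    cohort-level breakdowns. Ships a seedable synthetic-data generator so the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
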