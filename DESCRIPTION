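Package: analogseries
Title: Extraction and Prioritization of Analog Series from Compound Screening Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts matching molecular series (single-substitution-site analog
    series) from compound libraries by single acyclic bond fragmentation with
    optional retrosynthetic rules, computes per-compound assay hit-rate statistics
    with a quantile-cascade selection of extensively tested and frequently active
    compounds, scores each series by cumulative hit rate, assay overlap and
    inconsistent activity, prioritizes series by rank fusion, flags assay
    interference candidates with SMARTS substructure filters, and reads/writes a
    two-file tab-separated deposition format. A synthetic data generator produces
    analog libraries and simulated assay panels with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
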