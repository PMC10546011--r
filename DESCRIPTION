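Package: sgdem
Title: Speech-Graph Connectedness Analysis of Dementia Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the connectedness of spontaneous speech and
    relating it to dementia severity. Transcripts of picture-description tasks
    (CHAT or plain text) are mapped to word-trajectory directed multigraphs;
    connectedness is measured as the node counts of the largest connected
    component (LCC) and the largest strongly connected component (LSC),
    verbosity-controlled by a fixed-length moving window (30 words, step 3)
    whose per-window values are averaged. Cohort-level analysis provides an
    aggregate verbal-fluency z-score, chained-equation multiple imputation of
    missing fluency scores with predictive-mean matching, and multiple
    regression of severity scores (MMSE, MDRS, BDS) on education, fluency and
    connectedness with depression and onset-age controls, pooled across
    imputations by Rubin's rules. A synthetic-data module generates
    transcripts with tunable repetition structure and cohorts with known
    regression structure for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
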