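Package: fmribic
Title: Biclustering and Internal Quality Evaluation for Region-by-Time fMRI Matrices
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discover and evaluate biclusters in parcellated fMRI
    scans stored as Region x Time matrices. Implements the four internal
    quality indices used to compare biclustering solutions without ground
    truth (variance, mean squared residue, scaling mean squared residue and
    virtual error, together with the row-standardisation and virtual-pattern
    intermediates), reference biclustering algorithms covering three search
    strategies (exhaustive contiguous-column CCC, divide-and-conquer
    Bimax-style enumeration of all-ones submatrices, and a greedy
    conserved-state xMotifs-style search), clustering baselines expressed as
    biclusters, a synthetic scan generator with planted constant, shifting
    and scaling biclusters, and an evaluation pipeline with top-K selection,
    size summaries and correlation-based pattern-type inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
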