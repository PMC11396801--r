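Package: refstab
Title: Reference Gene Stability Analysis and Relative Quantification for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating RT-qPCR reference
    (housekeeping) genes from cycle-threshold (Ct) data. Implements
    standard-curve amplification-efficiency calibration, four expression
    stability statistics (geNorm M and pairwise-variation V, a NormFinder-style
    intra/inter-group variance decomposition, BestKeeper SD/CV screening, and
    the comparative delta-Ct method), geometric-mean rank aggregation into a
    RefFinder-style consensus, and 2^-ddCt relative expression profiling of
    target genes with per-timepoint significance testing. A seedable
    synthetic-data generator produces Ct datasets with known ground truth
    (designed-stable and designed-unstable genes, treatment and time-course
    structure) so every stage of the pipeline can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
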