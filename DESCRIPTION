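Package: epires
Title: Multilayered DNA-Methylation Analysis of Psychological Resilience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for finding and validating whole-blood
    DNA-methylation correlates of a tail-dichotomized psychometric trait
    (CD-RISC psychological resilience) on EPIC-like arrays. Implements
    percentile-subset differential methylation with empirical-Bayes moderated
    per-CpG linear models and dose-response consistency scoring, bump-hunting
    detection of differentially methylated regions with an area statistic and
    a permutation null, and a matched-triplet resampling random-forest
    classifier tuned by Youden's J. Ships a synthetic EPIC-like data generator
    with known spiked dose-responsive regions so every stage is testable
    without protected cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
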