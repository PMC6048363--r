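Package: sasptools
Title: Screen Normalization, Splicing Maps and Enrichment Analysis for
    Senescence Secretome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for the computational workflow behind RNAi screens for
    regulators of the senescence-associated secretory phenotype (SASP) and
    the splicing-factor follow-up they motivate. Implements plate-level
    normalization of 96-well screen readouts (two-way median-polish B-scores
    and control-based normalized percent inhibition), replicate-consensus
    hit calling, secondary-screen validation and K-means phenotype triage;
    percent-spliced-in (PSI) quantification from exon junction reads,
    delta-PSI testing and two-tier event shortlisting; RNA maps of
    RNA-binding-protein motif density around alternative exons with exact
    PWM p-values and moving-window Fisher enrichment; preranked gene-set
    enrichment (ES/NES/FDR); and a cross-tissue dichotomization procedure
    linking regulator expression to exon inclusion. A set of synthetic-data
    generators with known ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    limma,
    jsonlite,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
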