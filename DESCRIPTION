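Package: igcoat
Title: Multi-Immunoglobulin Coating Analysis of Gut Bacteria from Flow
    Cytometry and Sorted-Fraction Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies single-, double- and triple-immunoglobulin (IgA,
    IgM, IgG and IgG1-4) coating of intestinal bacteria. Converts
    bead-calibrated flow-cytometry event tables into absolute bacterial
    loads per gram feces and per-isotype-combination coating fractions;
    decontaminates FACS-sorted amplicon sequence variant (ASV) count
    tables against negative controls; classifies ASVs into coating
    categories across IgA-deficient/IgA-sufficient household pairs;
    converts sorted-fraction compositions into coated loads and family
    coating frequencies; calls flagellin, penta-/hexa-acylated LPS and
    butyrate production capability from KEGG ortholog profiles with an
    editable rule engine; and provides the paired nonparametric
    statistics layer (Wilcoxon signed-rank, Spearman, Fisher, FDR).
    Includes a synthetic cohort generator so the full pipeline is
    testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
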