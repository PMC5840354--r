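Package: phytojip
Title: JIP-Test Fluorescence, P700 Transmittance and Stress Phenomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plant abiotic-stress physiology experiments:
    parsing and JIP-test analysis of fast chlorophyll a fluorescence (OJIP)
    induction curves (Fv/Fm, relative variable fluorescence, initial slope,
    RC/ABS, the performance index PI(abs), area over the transient),
    820 nm transmittance kinetics as a P700 redox proxy, agronomic trait
    statistics (group summaries, percent change, one-way ANOVA with a
    protected LSD post hoc, Student's t tests, K+/Na+ ratio, electrolyte
    leakage, germination percentage), ddCt relative expression from qPCR Ct
    tables, and a GC-MS metabolite statistics chain (internal-standard
    normalization, log2 stress/control fold changes, up/down Venn
    classification, PCA, box-whisker summaries). Seeded synthetic-data
    generators with known ground truth make every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
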