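Package: sgzephys
Title: Biophysical Classification of Hippocampal Neural Progenitor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for electrophysiology-based staging of neural
    progenitor cells in the hippocampal sub-granular zone. Classifies cells as
    type 1 radial glia-like stem cells, type 2a transit-amplifying
    progenitors, or type 2b neuroblast-like progenitors from three whole-cell
    patch-clamp features (resting membrane potential, input resistance,
    membrane capacitance) via genotype-specific multinomial logistic
    regression fitted by maximum likelihood. Includes voltage-step
    current-voltage analysis with linear leak subtraction, pharmacological
    difference-current isolation and transient inward (sodium) current
    detection; fixed-radius clone calling from 3D lineage-tracing
    coordinates with clone-size distribution comparison; a statistical
    toolbox (two-way type II ANOVA with Sidak adjustment, exact Mann-Whitney
    U, phospho-intensity normalization); and seeded synthetic-data generators
    for every input so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
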