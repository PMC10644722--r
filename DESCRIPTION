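Package: inhibscreen
Title: Enzyme Inhibitor Screening, Kinetic Mechanism Selection, and
    Structure-Activity Similarity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for phosphatase inhibitor screening
    campaigns. Converts chromogenic absorbance readings into percent
    inhibition and potency estimates (IC50, pIC50, activity difference
    versus a reference inhibitor), fits substrate-by-inhibitor initial
    velocity surfaces globally to a bank of seven linear and parabolic
    inhibition mechanisms with reduced chi-squared model selection,
    computes binary molecular fingerprints and Tanimoto similarity
    matrices with cumulative-distribution-based fingerprint selection
    and t-SNE chemical space projection, and classifies compound pairs
    on structure-activity similarity maps into scaffold-hop, smooth-SAR,
    non-descript, and activity-cliff zones. Includes synthetic data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    ChemmineR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
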