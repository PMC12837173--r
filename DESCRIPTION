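Package: octaquant
Title: Quantification of Retinal Vasculature in OCT Angiography En-Face Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the retinal vasculature in en-face optical
    coherence tomography angiography (OCTA) scans and to compare vessel
    metrics between cohorts. Implements local adaptive binarization
    (Phansalkar, Niblack, Otsu), topology-preserving skeletonization,
    ETDRS-grid regional skeletonized vessel density for macula and optic
    nerve head scans, and foveal avascular zone (FAZ) area, perimeter and
    acircularity from traced outlines. A synthetic angiogram and cohort
    generator with known ground truth supports end-to-end validation, and a
    statistics layer fits linear mixed-effects diagnosis-by-quadrant models
    with post hoc contrasts, Benjamini-Hochberg adjustment, age
    stratification, FAZ regression and density-RNFL correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
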