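Package: RetiPhen
Title: Automated Phenotyping of the Retinal Vasculature from Vessel Segmentation Masks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures morphological image-derived phenotypes (IDPs) of the retinal
    vasculature from pixel-wise artery/vein segmentation masks and an optic-disc
    location. Vessel centerlines and branch points are extracted by topology
    preserving thinning, per-point calibers by the Euclidean distance transform,
    and seventeen phenotypes are computed per image: temporal arcade angles,
    median tortuosities, central retinal arteriolar/venular equivalents (revised
    Knudtson pairing), diameter medians and variabilities, vascular densities,
    bifurcation counts, and artery/vein ratios. Includes image quality-control
    gating, subject-level aggregation across eyes and visits, rank-based inverse
    normal transformation and covariate residualization, phenotypic/genetic
    correlation-structure comparison, a linear/logistic disease-association
    battery, and a seeded synthetic vasculature generator with exhaustive ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Visualization, ImageProcessing, Regression
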