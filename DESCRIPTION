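Package: octamorph
Title: En Face OCTA Vascular Morphometry and Mixed-Model Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of en face optical coherence
    tomography angiography (OCTA) of the macula and for the accompanying
    clinical-cohort statistics. The imaging chain turns a stack of noisy,
    motion-corrupted en face frames into a single averaged angiogram
    (inhomogeneity correction, translation/affine/elastic registration,
    intensity normalisation, mean or maximum projection), segments the
    microvasculature, extracts single-pixel centerlines, builds a vessel
    graph with Horton-Strahler ordering to separate arterioles/venules
    from capillaries, and computes perfusion density, vessel density,
    vessel diameter, fractal dimension, two tortuosity indices, and
    foveal avascular zone (FAZ) shape metrics with Littmann-Bennett
    ocular-magnification correction. The statistical chain covers
    random-forest imputation of mixed-type data, univariate screening
    (Welch t and exact contingency tests), linear/logistic/multinomial
    mixed models with a per-patient random intercept, correlation-based
    predictor pruning, maximal-model backward-AIC selection, and
    leave-one-out cross-validated ROC analysis. Synthetic vascular
    phantoms with full ground truth and synthetic cohorts with a known
    within-patient correlation structure are provided so that every
    stage can be validated against generating values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    lme4,
    randomForest,
    pROC,
    pracma,
    car,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
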