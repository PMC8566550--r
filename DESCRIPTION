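Package: synaptoquant
Title: Quantitative Analysis of Synaptic pHluorin, Glutamate and Calcium
    Imaging and Worm Chemotaxis Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fluorescence time series from genetically
    encoded sensors (synaptopHluorin, iGluSnFR, GCaMP) and for analysing
    CO2-evoked locomotor behavior in C. elegans. Implements dF/F
    normalisation, moving-average filtering, responder classification and
    exclusion gates; inference of vesicular lumenal pH and probe surface
    fraction from dual NH4Cl/MES pHluorin calibrations by solving a
    two-equation ratiometric model, together with the pH-dependent
    exocytosis correction factor used to compare evoked responses across
    genotypes; worm-track kinematics (instantaneous speed, heading change,
    high-angle-turn detection, population time series) and the chemotaxis
    avoidance index; group comparisons by Kruskal-Wallis with Dunn's
    post-hoc test and one-way ANOVA with Dunnett's test; and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
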