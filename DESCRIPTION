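Package: frontscan
Title: Acoustic and Hydrographic Analysis Across Ocean Thermal Fronts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the joint analysis of multifrequency echosounder
    backscatter and hydrography across ocean thermal fronts. Implements the
    full echogram cleaning chain (sound-speed and absorption re-correction,
    near-field and seabed exclusion, background and impulse noise removal,
    linear-domain smoothing and thresholding), dB-differencing classification
    of integration cells into fish and macrozooplankton, NASC echo
    integration, rule-based water-mass classification, maximum-gradient front
    localization from CTD sections and SST series, Brunt-Vaisala
    stratification, three-frequency RGB composites, and the ecological
    statistics used to relate abundance to frontal structure (Kendall
    correlation with Benjamini-Hochberg adjustment, diversity indices,
    Bray-Curtis ANOSIM). A synthetic-data module generates echograms, CTD
    transects and trawl catches with planted ground truth so the whole
    pipeline is testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, data.table, vegan, geosphere,
    png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hydrography.R'
    'echogram.R'
    'classify.R'
    'composites.R'
    'ecostats.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
    'frontscan-package.R'
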