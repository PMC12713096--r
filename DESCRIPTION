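Package: soilstoich
Title: Four-Decade Soil C:N:P Stoichiometry Change Analysis for Cropland Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify long-term changes in soil carbon, nitrogen and
    phosphorus stoichiometry across 0-100 cm cropland profiles sampled in two
    eras. Legacy genetic-horizon profiles are harmonized to fixed depth
    intervals by best-fit depth-concentration regression (linear, logarithmic,
    exponential, power), with conversion uncertainty quantified by residual
    bootstrap and horizon-boundary perturbation. Molar C:N, C:P and N:P ratios
    and their absolute and relative changes are computed per layer and per
    profile, optionally on an equivalent-soil-mass basis. Cumulative
    management inputs (straw, crop residues, manure, mineral fertilizer) and
    climate accumulation and seasonality metrics are derived from annual
    ledgers and monthly series. Driver attribution combines variance-inflation
    screening, partial correlation, random-forest permutation importance,
    logarithmic threshold detection and one-way ANOVA with compact letter
    displays. A synthetic-data generator with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
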