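Package: canopyflux
Title: Big-Leaf Canopy Conductance Estimation for Vineyards with a
    Penman-Monteith Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates grapevine canopy conductance to water vapor from leaf
    stomatal conductance, leaf area index, net radiation and vapor pressure
    deficit with a big-leaf biophysical model, and validates it against the
    reference canopy conductance obtained by inverting the Penman-Monteith
    equation driven by measured canopy transpiration. Includes the FAO-56
    micrometeorological primitives (vapor pressures, psychrometric constant,
    air density, pressure from elevation), the data-conditioning rules used
    in field campaigns (unit conversion by molar density of air, canopy-side
    aggregation, daylight/radiation exclusion, interquartile-range outlier
    screening), a complete model-agreement statistics suite (RMSE, MAE,
    aggregate bias, correlation, ordinary least squares with an intercept
    test, regression through the origin, Cohen's d with pooled standard
    deviation, U1 non-overlap, coefficients of variation), and a seeded
    generator of Mediterranean-summer diurnal vineyard datasets with known
    ground-truth conductance so the full pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
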