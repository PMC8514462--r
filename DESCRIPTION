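Package: cropdiv
Title: National-Scale Crop Diversity Change Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying change in national crop diversity from
    long-format harvested-area tables in the FAOSTAT dialect. Computes
    per-country-per-year crop-group richness, Shannon diversity and Pielou
    evenness; fits two-breakpoint piecewise-linear (segmented) regressions
    to diversity time series and derives onset, duration and rate
    indicators of diversity change; analyses multivariate composition
    change with Bray-Curtis dissimilarities, non-metric multidimensional
    scaling and permutational MANOVA; fits latitudinal richness gradients
    and Human Development Index mixed models with variance partitioning.
    Includes a synthetic data generator with known ground truth for
    end-to-end validation, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
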