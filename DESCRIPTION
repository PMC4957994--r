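Package: winterniche
Title: Thermal Niche Statistics for Wintering Birds from Upper-Quantile
    Abundance Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the limiting effect of minimum winter temperature on the
    maximum potential abundance of wintering birds. Fits quadratic quantile
    regressions of relative abundance (frequency of detection in repeated
    transects) on standardized temperature at configurable percentiles using
    an exact interior-point linear-programming solver, screens models by
    Koenker-Machado pseudo-R-squared and asymmetric-Laplace AIC against the
    intercept-only null, and derives per-species thermal-niche statistics:
    the environmental preferred temperature (vertex of the 95th-percentile
    curve), the abundance-weighted mean temperature of the occupied cells,
    and the thermal breadth (normalized area under the upper-quantile
    curve). Includes an across-species meta-analysis battery (t tests,
    paired tests, repeated-measures linear contrast, Holm-corrected
    per-species tests, correlations, summary tables), a binomial
    detection-survey simulator producing wedge-shaped abundance-temperature
    point clouds with known ground truth, delimited-text readers and
    writers, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
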