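Package: nresponse
Title: Yield Response to Nitrogen and Economic Optimum N Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits corn yield response to nitrogen fertilizer rate with quadratic
    and quadratic-plus-plateau models, derives the economic optimum N rate (EONR)
    and yield at the optimum (YEONR) from the fitted curve or from fine-increment
    return-to-nitrogen (RTN) scans, pools multi-year trials into site mean
    recommendations, scores simulated-versus-observed agreement with RMSE and
    relative RMSE bands, and explains year-to-year EONR variability with
    precipitation-window regressions. Includes a seeded synthetic multi-year
    trial generator with rotation-dependent soil N supply, precipitation-driven
    exponential fertilizer N loss and closed-form true optima for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
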