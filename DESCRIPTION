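Package: regtrend
Title: Regularized Trend Estimation for Short Noisy Abundance Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and estimation of population declines from short,
    noisy time series of abundance or density estimates, as used in
    conservation monitoring of cetaceans and other hard-to-survey taxa.
    Provides a lognormal data-generating simulator for abundance-estimate
    series expressed as ratios to a baseline, a no-intercept log-linear
    trend regression fitted by maximum likelihood or by maximum a
    posteriori estimation under an informative normal prior or a
    weakly-informative Cauchy prior (scale-mixture EM), and a Monte Carlo
    engine computing power, type-I, type-S and type-M error rates, bias
    and confidence-interval coverage over factorial scenario grids.
    Includes case-study tools for real series: annual growth rates and
    expanding-window stability analyses, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
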