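Package: ivivcr
Title: Level A In Vitro-In Vivo Correlation for Extended-Release Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating level A in vitro-in vivo
    correlations (IVIVC) for extended-release oral formulations. Fits Hill and
    Weibull dissolution models with AIC selection, estimates per-subject unit
    impulse responses from an immediate-release reference arm by polyexponential
    fitting with first-order absorption stripping, deconvolves extended-release
    plasma profiles to cumulative fraction absorbed by constrained numerical
    deconvolution, fits a nonlinear Emax time-scaling correlation between in
    vitro and in vivo time, predicts plasma concentration profiles by
    convolution, and evaluates FDA/EMA prediction-error criteria including
    leave-one-out cross-validation. Includes a synthetic crossover-study
    generator with known ground truth, noncompartmental analysis, and the f2
    dissolution similarity factor.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, minpack.lm, pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
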