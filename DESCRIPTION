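Package: recmotion
Title: Recurrent Network Models of Visual Motion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and dissecting recurrent-network models of
    velocity-tuned responses in the primate motion pathway. Provides
    generators for one-dimensional moving noise, drifting gratings and bar
    noise; a synthetic generator of MT-like target firing-rate patterns
    (band-pass speed tuning, direction selectivity, response latency and
    ramp); an Elman recurrent network trained with exact
    backpropagation-through-time; tuning-curve measurement with direction
    selectivity and speed tuning indices; reverse-correlation
    characterization (spike-triggered average and covariance, most
    informative filter selection, static nonlinearities, separable
    linear-nonlinear simulation, Fourier spectra); and connectivity
    analyses (simple/complex modulation ratio, direct versus indirect
    input, delay-line speed prediction, weight sorting, input-weight
    principal components).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
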