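Package: mepsctools
Title: Detection, Model Fitting and Density-Peak Clustering of Miniature EPSCs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts miniature excitatory postsynaptic currents (mEPSCs) from
    whole-cell voltage-clamp recordings and decides how many types of excitatory
    synaptic input a neuron receives. Traces are conditioned by Butterworth
    high-pass de-trending, low-pass de-noising and a cascade of band-stop filters
    removing mains interference and its harmonics; events are detected by a
    robust mean-minus-4-SD threshold on percentile-trimmed data, fitted with a
    four-parameter linear-rise/exponential-decay model by Levenberg-Marquardt
    least squares, screened by plausibility bounds and iterated principal-
    component outlier removal, gated by per-cell stationarity F-tests with
    Bonferroni correction, and finally clustered in the {log amplitude,
    log decay} plane by density-peak clustering with an automatic cluster-count
    rule. A seeded synthetic-recording generator with known ground truth
    (Poisson event timing, log-normal parameter populations, Gaussian noise,
    line interference, baseline drift) supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
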