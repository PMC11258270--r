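Package: glucotwin
Title: Mechanistic Glucose-Insulin Modelling for a Pancreas-Liver
    Microphysiological System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital twin of glucose regulation in a two-compartment
    pancreas-liver microphysiological system (MPS). Implements a coupled
    fast (hours) / slow (weeks) ordinary differential equation model of
    glucose and insulin exchange between a liver-spheroid and a pancreatic
    islet compartment, event-driven simulation of on-chip culture
    protocols (medium exchanges, glucose tolerance tests, insulin spikes),
    weighted least-squares calibration with chi-squared model rejection,
    simulated-annealing collection of acceptable parameter sets,
    uncertainty-envelope prediction, discriminating-dose experimental
    design, low-hydrocortisone response prediction, reproducibility
    statistics (trapezoidal AUC, maximum coefficient of variation,
    ICC(2,1)), and synthetic-study generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
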