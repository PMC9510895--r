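Package: doxpop
Title: Population Dynamics of Breast Cancer Cells Under Doxorubicin Treatment
Version: 0.1.0
Authors@R:
    person("doxpop", "maintainers", email = "maintainers@doxpop.example", role = c("aut", "cre"))
Description: Mechanistic modelling of MCF-7 breast cancer cell population
    dynamics under single and repeated doxorubicin dosing. Implements a
    compartmental ordinary-differential-equation model in which each drug
    dose partitions the proliferating population into surviving cells and an
    irreversibly damaged subpopulation that transitions from proliferation
    to drug-induced death at an exponentially decaying net rate. Provides
    trajectory preprocessing (truncation, discontinuity normalization,
    median-filter outlier removal), bounded nonlinear least-squares
    calibration with asymptotic confidence intervals, quality-of-fit and
    rank-sum statistics, empirical concentration-parameter formulas with
    Latin hypercube uncertainty envelopes, and a synthetic time-course
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
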