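Package: luxchar
Title: Characterization of an HSL-Inducible Promoter Device Across DNA Copy-Number Contexts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the quantitative characterization of a LuxR/HSL
    inducible promoter device from microplate kinetic data across DNA
    copy-number contexts. Converts raw OD600 and fluorescence time series into
    per-cell reporter synthesis rates (S_cell) normalized to a common detector
    gain, expresses promoter activity in Relative Promoter Units (RPU) against
    the J23101 reference, estimates DNA copy number indirectly from
    constitutive reporter devices, fits Hill dose-response functions to
    induction curves, and infers the transfer function of the luxI promoter
    with respect to the HSL-LuxR activated complex (K_A, n_A, alpha_lux) via a
    steady-state gene-expression model. Includes a synthetic plate-reader data
    generator with a ground-truth manifest for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SystemsBiology, SyntheticBiology, TimeCourse, Regression
RoxygenNote: 7.3.3
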