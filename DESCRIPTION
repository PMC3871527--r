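Package: dcepk
Title: DCE-MRI Transvascular Parameter Mapping with Nested-Model Selection
    and Test-Retest Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired test/retest dynamic contrast-enhanced (DCE) MRI
    studies of an orthotopic rat glioma and analyses them with a nested
    pharmacokinetic model-selection pipeline. Includes Look-Locker T1 mapping,
    dual-echo T2*-corrected conversion of signal to contrast-agent
    concentration, voxelwise fitting of three nested kinetic models (plasma
    volume only; Patlak influx; extended Tofts with backflux) with sequential
    F-test model selection, apparent diffusion coefficient mapping, and
    cohort-level test-retest statistics (paired t-tests, one-way ANOVA with a
    planned contrast of early versus late treatment groups).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
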