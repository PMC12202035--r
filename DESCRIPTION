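Package: cedtrace
Title: Infusate Distribution Volumetry and Trial Analytics for
    Convection-Enhanced Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing convection-enhanced delivery (CED) of
    therapeutics co-infused with a gadolinium tracer in brainstem glioma
    trials. Implements subtraction-based MRI volumetry of the tracer
    distribution volume (rigid registration, reference-structure intensity
    normalisation, thresholded difference segmentation), per-patient tumor
    coverage metrics (Vd/Vi ratios, covered fraction of the FLAIR-defined
    lesion), Kaplan-Meier overall-survival endpoints under alternative
    lost-to-follow-up policies, and a simulator of an accelerated titration
    design with rule-triggered transition to a standard 3+3 dose escalation.
    A synthetic phantom generator provides ground-truth imaging and cohort
    data so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
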