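Package: ukaspect
Title: Standardized SPECT/CT Evaluation of Unicondylar Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a standardized evaluation of bone tracer uptake and
    component position in patients after unicondylar knee arthroplasty (UKA)
    imaged with SPECT/CT. Implements a 24-region periprosthetic localization
    scheme with per-region summary statistics and background-normalized uptake
    ratios, landmark-based anatomical coordinate frames with signed projected
    component angles (varus-valgus, flexion/slope, axial rotation, rotational
    mismatch, tibiofemoral angle), intraclass-correlation reliability analysis
    of observer ratings, and a digital phantom generator producing volumes,
    landmark cases and rater tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
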