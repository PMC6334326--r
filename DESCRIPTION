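Package: cevalidate
Title: Analytical Method Validation for Capillary Electrophoresis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the statistical validation of capillary electrophoresis
    (CE) drug assays in the ICH style: simulation of electropherograms with a
    known corrected-area response law, peak metrology (migration time,
    corrected peak area, theoretical plate number, asymmetry), calibration
    linearity with a lack-of-fit ANOVA partition, limits of detection and
    quantitation, content and recovery computations, precision summaries, and
    a 15-run seven-factor Plackett-Burman robustness screen assessed with the
    Youden-Steiner sqrt(2)*S criterion. Results are tibbles that compose with
    the pipe; fitted objects provide tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
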