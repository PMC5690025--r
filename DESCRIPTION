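Package: phantomiq
Title: Automated Imaging Quality Assurance for Linac On-Board Imagers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to automate routine imaging quality assurance (QA) for
    linear accelerators: a seeded digital phantom generator emulating a
    four-section image-quality phantom with injectable cone-beam CT artifacts
    (rings, scatter, beam hardening, crescent), classical image-quality
    metrics (contrast-to-noise ratio, modulation transfer function by the
    standard-deviation method, uniformity and noise), a 99-feature texture
    battery (first-order statistics, gray-level co-occurrence matrices,
    multi-scale filter responses), one-vs-all linear support-vector-machine
    artifact classification with sequential forward feature selection under
    stratified ten-fold cross-validation, Winston-Lutz isocenter analysis by
    threshold-band centroiding, and daily/monthly QA reporting against
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
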