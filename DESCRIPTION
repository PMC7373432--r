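Package: sensorymap
Title: Psychophysics and Percept Mapping for Epidural Spinal Cord Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sensory percepts evoked by epidural spinal
    cord stimulation in upper-limb amputees: adaptive one-up three-down
    staircase threshold tracking, maximum-likelihood cumulative-normal
    psychometric fitting with parametric-bootstrap goodness-of-fit (pTLR),
    just-noticeable-difference estimation, free magnitude estimation with
    intensity-model comparison and binned discriminability, calibrated
    percept-drawing analytics (centroid, area, overlap, weekly stability),
    modality classification and dermatome proportion tables, threshold-charge
    stability statistics with AR(1)-error trend regression, and lead-migration
    geometry. Includes a synthetic-study generator with known ground truth so
    every stage is testable end to end.
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
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
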