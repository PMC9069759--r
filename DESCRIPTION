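Package: famtrans
Title: Intergenerational Transmission of BMI and Educational Attainment in Family Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural equation modelling of the joint intergenerational
    transmission of body mass index (BMI) and educational attainment (EA)
    in nuclear families with up to two parents and six offspring. Fits the
    family path model by full-information maximum likelihood (FIML) under
    family-level missingness, decomposes standardized effects into direct
    and indirect (spousal- and within-person-correlation mediated) paths,
    tests gender-equality constraints on transmission coefficients by
    likelihood-ratio tests with Bonferroni control, and simulates
    Netherlands-Twin-Register-like synthetic family datasets for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
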