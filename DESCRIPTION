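Package: spongecolor
Title: Structure-to-Colour Analysis of Non-Iridescent Plumage from
    Small-Angle X-Ray Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to trace non-iridescent structural plumage colour back to
    the nanostructural periodicity of the spongy keratin layer inside feather
    barbs. Reduces matrix-mode small-angle X-ray scattering (SAXS) detector
    frames to one averaged scattering curve per sample (azimuthal averaging,
    robust outlier filtering, intensity normalisation), fits a constrained
    double-Gaussian peak model to the Porod-transformed curve, converts peak
    positions to Bragg repeat distances and predicted hue via the
    volume-averaged refractive index, summarises reflectance spectra
    (brightness, UV chroma, hue), and runs the cohort statistics linking
    nanostructure to colour (sex standardisation, backward-elimination linear
    models with term reintroduction, varimax orthogonalisation,
    male-coefficient residual dichromatism, paired estimated-versus-measured
    hue comparison, between-round repeatability). A synthetic-cohort generator
    produces detector frames, replicate scattering curves and triplicate
    reflectance spectra with known ground truth so that every stage is
    testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
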