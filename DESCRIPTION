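Package: retinox
Title: Hyperspectral Retinal Oximetry by Least-Squares Hemoglobin Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates intravascular oxygen saturation of retinal vessels
    from hyperspectral fundus image cubes. Vessel optical density spectra
    are computed against flanking background references and unmixed by a
    modified Beer-Lambert least-squares fit of oxy- and deoxyhemoglobin
    molar extinction over a deterministic 28-wavelength selection.
    Includes a synthetic hyperspectral fundus generator with known
    ground-truth saturations emulating a rabbit retinal-vein-occlusion
    study (paired pre/post cohorts, laser-control arms, recannulation
    time courses), paired cohort statistics, pseudocolor saturation maps,
    and ENVI-style and TIFF-stack cube input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
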