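Package: pedopress
Title: Pedobarographic Analysis of Walking Elephant Pressure-Plate Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for gridded foot-pressure recordings of walking
    elephants: spatio-temporal isolation of individual footsteps from plate
    recordings, rigid registration of footprints to per-foot templates,
    Gaussian-kernel extraction of peak pressures at anatomical regions of
    interest with a one-pixel placement sensitivity analysis, centre-of-pressure
    (COP) trajectory computation and averaging, and trajectory comparison via
    axis-wise Pearson correlation, RMSE and ordinary Procrustes analysis with
    scaling and reflection (RMSD). Includes a synthetic pressure-record
    generator with analytic ground truth (step masks, COP paths, regional peak
    pressures) emulating the plate and gait geometry of the study system, plus
    descriptive gait statistics (Froude number, weighted means, cohort
    summaries) and plain-text readers/writers for all record and result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
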