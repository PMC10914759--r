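Package: leap
Title: Simulation and Analysis of a Serum Protease-Activity Biosensor Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying an 18-sensor serum protease activity panel
    for lung-cancer detection: a synthetic-data generator emulating the
    cohort design (donor demographics, plate-read fluorescence with a
    per-plate standard curve), quantitation of fluorescence to released
    peptide-TCPP concentration with below-LLOQ censoring, cohort statistics
    (percent difference, per-timepoint t tests, Hotelling's T-squared,
    Clopper-Pearson intervals, replicate precision), an island-model linear
    genetic programming classifier with biased ensemble operating points and
    ablation-based sensor impact ranking, and a deterministic
    screening-triage model of LDCT outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
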