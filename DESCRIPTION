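Package: wmglia
Title: Interferon-Responsive Glial States in Aging White Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying interferon-responsive oligodendrocyte and
    microglia states induced by CD8+ T cells in aging murine white matter.
    Implements per-cell quality-control filter chains for plate-based
    (Smart-seq2) and droplet single-cell RNA-seq, marker-signature scoring
    and cell-state assignment, Wilcoxon rank-sum marker ranking, per-sample
    compositional analysis with a beta-binomial likelihood-ratio test, and
    a 20-micrometre spatial proximity analysis between cell categories with
    a matched random-cell null and paired testing. Ships a synthetic-data
    generator (gamma-Poisson counts, Dirichlet-multinomial compositions,
    parent-offspring point patterns) with planted ground truth for
    calibration and power studies, plus a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
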