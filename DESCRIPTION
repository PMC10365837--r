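Package: axonquant
Title: Quantification of Axonal Transport, Exocytosis and Synaptic Morphometry
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying presynaptic physiology in reconstituted
    corticostriatal networks and brain tissue: kymograph-based axonal
    transport metrics (segmental velocities, directional net flux, linear
    flow, directionality), pHluorin exocytosis event detection with a
    reference-normalized activity statistic, electron-microscopy presynaptic
    morphometry with 40-nm distance zones from the active zone, difference-of-
    Gaussians puncta colocalization and PLA dot densities, paired-pulse ratio
    analysis of evoked EPSCs with resistance-based quality control, and a
    statistical decision workflow (ROUT outlier removal, Shapiro-Wilk gate,
    parametric/non-parametric test selection with post hocs). Seeded
    simulators generate every input with exported ground truth so the whole
    pipeline is testable without microscope or patch-clamp data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    polyclip,
    pracma,
    EBImage,
    emmeans,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
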