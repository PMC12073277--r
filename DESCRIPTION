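Package: asdkit
Title: Stability and Molecular Mobility Analysis of Amorphous Solid Dispersions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the physical stability and molecular mobility of
    amorphous solid dispersions (drug-in-polymer formulations). Fits time-domain
    NMR observables: saturation-recovery magnetization curves (mono- and
    bi-exponential, with information-criterion model selection and proton-counting
    phase assignment), free-induction-decay decomposition into rigid (Gaussian)
    and mobile (exponential) components, and multi-process
    Bloembergen-Purcell-Pound spin-lattice relaxation curves with Arrhenius
    correlation times. Estimates crystallite sizes from diffraction peak widths
    (Scherrer) and spin-diffusion detectability lengths. Computes molecular
    dynamics trajectory observables: intermolecular pair distribution functions,
    geometric hydrogen-bond detection and network censuses, cluster analysis,
    torsional angle distributions and angular correlation functions. A synthetic
    data generator with known ground truth replaces instruments and simulation
    engines so every stage is testable end to end.
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
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
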