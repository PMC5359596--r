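Package: opticond
Title: Simulation and Analysis of Electro-Optical Membrane Conductance Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for voltage-sensitive-dye (VSD) imaging assays in which a
    test current pulse polarizes the cell membrane and the ratio of local
    fluorescence responses before and after drug administration measures the
    relative membrane resistance (Rd/Rc) and conductance (Gd/Gc) by Ohm's law.
    Includes a physics-based simulator of the two-passage, two-frame imaging
    protocol (cosine membrane polarization along the field axis, RC charging,
    Hill-type drug conductance with optional rectification, dye bleaching,
    shot and camera noise), the full image-analysis pipeline (integer-shift
    registration, binning, membrane-ring shape masks, per-pixel dF/F maps,
    paired-pixel scatter slopes), four-parameter logistic concentration-
    response fitting with EC50/IC50 estimation, and screening quality-control
    statistics (Z and Z' factors, coefficient of variation, EC50 fold change).
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
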