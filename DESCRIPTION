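Package: cnmtarget
Title: Individualized fMRI-Connectivity TMS Targeting with a Core Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes individualized transcranial magnetic stimulation (TMS)
    targets in the dorsolateral prefrontal cortex (DLPFC) from functional MRI
    connectivity using a core network model (CNM): eight seed regions whose
    voxelwise Pearson connectivity maps are combined with sign reversal of the
    regulated (amygdala, subgenual cingulate) seeds. Includes the supporting
    denoising steps (nuisance regression, bandpass filtering, framewise
    displacement scrubbing), top-K target selection with group overlap and
    peak-distance summaries, within-subject repeatability statistics (segment
    splitting, masked spatial correlation, Fisher Z inference, exponential
    scan-time model), covariate-adjusted outcome correlation, and a fully
    self-contained synthetic-data generator with exported ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    purrr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    minpack.lm,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
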