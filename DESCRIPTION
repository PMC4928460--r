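Package: slfomap
Title: Systemic Low-Frequency Oscillation Mapping and Tissue-Stratified
    Voxel Statistics for Resting-State BOLD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise lagged cross-correlation mapping of resting-state
    BOLD timeseries against a venous seed regressor (the "maxcc" map),
    amplitude of low-frequency fluctuation (ALFF) mapping, equal-count
    decile binning of valid voxels, tissue-distribution curves with slope
    statistics, and a swapped-seed null control. Includes a synthetic 4D
    BOLD phantom generator with known ground-truth delay and mixing
    fields so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
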