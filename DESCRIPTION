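Package: cuemap
Title: Cue Cell Analysis for Entorhinal Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of landmark-coding ("cue") cells
    in medial entorhinal cortex recordings from virtual linear tracks and
    open arenas. Builds occupancy-normalized spatial, two-dimensional and
    head-direction firing rate maps with velocity gating; detects spatial
    firing fields against circular-permutation shuffle nulls; computes the
    template cross-correlation cue score with pooled shuffle thresholds,
    side-specific and bilateral variants; computes classic grid, border,
    head-direction and split-half stability scores; quantifies population
    sequences with a ridge/background statistic and a field-shuffle null;
    analyses cue-removal perturbations and the calcium-imaging branch
    (dF/F, transients, in/out-of-field periods, cross-environment
    commonality); and ships synthetic-data generators with ground-truth
    labels so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    yaml,
    rlang,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
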