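Package: dynparcel
Title: Dynamic States of Seed-Based Brain Parcellation from Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies recurring dynamic states of brain parcellation for a
    seed voxel from resting-state fMRI. Sliding-window k-means parcellations
    of the masked volume are binarized at the seed, compared with the Dice
    coefficient, and aggregated by average-linkage hierarchical clustering
    into dynamic states; states passing a dwell-time filter are summarized as
    voxelwise stability maps. Includes a split-half evaluation battery
    (Hungarian matching of state maps by Pearson correlation, reproducibility
    scores, deterministic and chance fingerprinting, dwell-time comparison)
    and a synthetic 4D BOLD generator with planted, temporally switching
    parcellations for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
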