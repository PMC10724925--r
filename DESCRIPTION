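Package: otstitch
Title: 3D Cell Instance Reconstruction from 2D Masks via Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D cell instance segmentations from z-stacks of
    independently labeled 2D masks, as produced by any per-slice 2D
    segmentation model. Cell slices in adjacent layers are put in
    correspondence by solving an exact discrete optimal transport problem
    whose cost is one minus the pairwise Jaccard index; a per-pixel
    rejection vote over orthogonal (YZ/XZ) mask stacks prevents stacked
    cells from being merged. An optional 2-Wasserstein boundary
    interpolation morphs matched cell slices to reconstruct the internal
    layers of anisotropic volumes. Includes instance-level
    precision/recall/average-precision evaluation, a deterministic
    synthetic 3D cell scene generator for end-to-end testing, and readers
    and writers for multi-page TIFF label volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
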