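Package: surfmorph
Title: Surface-Based Cortical Morphometry with Random-Field-Theory Cluster
    Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Vertex-wise general linear models of cortical thickness,
    surface area and cortical volume on triangulated surface templates,
    with nested age-model selection, random-field-theory cluster
    correction for non-isotropic fields, a spatial-overlap statistic for
    thickness/area difference maps with a simulation null, and the
    decomposition of volume differences into thickness- and area-driven
    components. Includes readers and writers for FreeSurfer binary surface
    and curvature files, surface-based heat-kernel smoothing, and a
    synthetic two-group cohort generator with planted effect clusters for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
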