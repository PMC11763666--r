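Package: holocount
Title: Lensless In-Line Holographic Microscopy Simulation and Yeast Cell
    Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for lensless in-line
    holographic microscopy of yeast cells.  Provides paraxial
    spherical-wave hologram simulation from a point-source LED geometry,
    background normalization, single-step holographic reconstruction,
    iterative twin-image removal by constrained phase retrieval,
    multi-hologram mosaic stitching via multi-scale feature matching and
    least-squares affine fitting, circular-Hough-transform cell detection
    and counting, and dilution-series concentration calibration against
    reference counts.  Includes a seeded synthetic-data generator (circle
    cells, USAF-1951 style bar targets, multi-LED capture stacks) so the
    whole pipeline runs without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
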