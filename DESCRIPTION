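Package: stereoloc
Title: Rod-Based Stereotactic Localizer Geometry, Localization and Error Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating rod-based stereotactic
    localizer frames that carry fiducial panels on only the left and right
    sides of the head frame (bipanel systems). Provides the classic
    N-localizer bipanel plus three richer panel geometries (M, F and Z),
    enumeration of the three-bar localization sets each panel offers,
    N-localizer and Sturm-Pastyr style reconstruction of 3D points from 2D
    image fiducials, weighted overdetermined fitting of the image-to-frame
    transform with fiducial identification checks, a synthetic CT slice
    renderer with DICOM export and centroid-based fiducial detection, and a
    Monte Carlo study of how fiducial localization noise propagates into
    target error across slice heights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
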