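Package: cyclorama
Title: Digital Unrolling of Deformed Tubes in 3D Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digitally unrolls deformed tubes of non-uniform wall thickness
    imaged as 3D grey-value stacks (e.g. micro-CT of intact colons, tooth
    roots, rolled films). The tube wall on each cross section is meshed with
    virtual electrostatic field lines traced between oppositely charged
    inner and outer boundary contours; the lines define local wall thickness
    and a family of nested onion-like re-slicing surfaces at fixed relative
    depths, which are mapped onto a stack of equal-sized planar panoramas
    ('cycloramas'). An inverse mapping carries annotations drawn on the
    panoramas back into the original voxel grid. Includes a synthetic
    deformed-tube phantom generator with ground-truth markers, readers and
    writers for multi-page TIFF stacks, ImageJ ROI zip archives and a JSON
    contour dialect, and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
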