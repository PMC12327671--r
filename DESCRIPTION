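Package: hurgb
Title: Multi-Component HU-to-RGB Preprocessing of Brain CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Preprocesses single non-contrast head computed-tomography
    slices for intracranial-hemorrhage review and classification. A sweep
    of narrow Hounsfield-unit display windows is applied through a sigmoid
    intensity transfer; the hemorrhage window is selected automatically
    from the largest drop in boundary-point count between consecutive
    windows; skull, cerebrospinal-fluid, white-matter and gray-matter
    suspect regions are derived by binary-mask exclusion with fixed HU
    caps; and the components are rendered as RGB images with an adaptive
    red channel encoding hemorrhage density. Includes a minimal DICOM
    reader, a digital head phantom generator with ground-truth masks, and
    command-line drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    optparse,
    png,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
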