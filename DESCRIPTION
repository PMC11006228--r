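Package: octhist
Title: Barcode-Guided Registration of Histology Sections to OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the nine-degree-of-freedom affine mapping (three rotations,
    three translations, per-axis shrinkage) between a 2D histology section and a
    3D optical coherence tomography (OCT) volume from photobleached fiducial
    barcodes written into a fluorescent embedding gel. Provides plane-map
    composition and decomposition, barcode pattern design and line-to-plane
    correspondence decoding, least-squares plane estimation with surface-based
    depth resolution, multi-section joint fitting, automated fine alignment by
    masked normalized cross-correlation, oblique volume reslicing, focus-stack
    fusion, surface detection, SNR masking, H&E stain color normalization, and
    construction of co-registered OCT/H&E image pairs. A synthetic skin phantom
    generator with exhaustive ground truth makes every stage verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    tiff,
    png,
    EBImage,
    minpack.lm,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
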