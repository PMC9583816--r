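Package: wvtomo
Title: Multicolor Wide-Field Large-Volume Tomography Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Computational pipeline for multicolor wide-field large-volume
    tomography (WVT) of whole brains: three-phase optical-sectioning
    structured-illumination (SIM) and wide-field (WF) reconstruction,
    detection-plane geometry for chromatic-aberration-aware triple-channel
    imaging, similarity-transform co-registration of color channels,
    DAPI-cytoarchitecture-driven automatic brain contour recognition with
    minimum-imaging-region mosaic planning, acquisition accounting (mosaic
    counts, data volume, imaging time), and triple-channel soma
    co-location and atlas-region quantification. Includes a synthetic
    phantom-brain generator that exercises the full pipeline with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
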