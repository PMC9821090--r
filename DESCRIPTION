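Package: fazkit
Title: Automated Foveal Avascular Zone Extraction from En Face OCTA Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic extraction of the foveal avascular zone (FAZ) from
    en face optical coherence tomography angiography (OCTA) images by a
    morphological dilation-erosion pipeline with FFT bandpass denoising,
    together with a batch annotation workflow that turns extractions into
    binary label images for training semantic-segmentation networks
    (flip/rotation amplification, nearest-neighbour resizing and cropping),
    a synthetic OCTA scene generator with known ground-truth FAZ masks, and
    a segmentation-agreement evaluation suite (magnification-corrected
    areas, per-subject coefficients of variation, Jaccard and Dice indices,
    false-negative/false-positive pixel accounting, and a nonparametric
    method-comparison battery).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
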