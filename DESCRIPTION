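Package: fsnlb
Title: Frequency-Selective Non-Linear Blending for Non-Enhanced Brain CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the "best contrast" post-processing algorithm for
    non-enhanced brain CT: the image is split into low- and high-frequency
    bands, a non-linear attenuation scaling centred on a chosen Hounsfield
    level is applied to the low (contrast) band only, and the bands are
    re-merged, amplifying subtle gray-white attenuation differences such as
    early ischemic edema without amplifying image noise. Ships a seeded
    single-slice digital brain phantom with an ASPECTS-style region template
    and injectable hypoattenuating lesions, an automated mirror-comparison
    reader (region measurements, ASPECTS scoring, lesion area, CNR), and the
    diagnostic-accuracy statistics layer (exact binomial confidence
    intervals, Fisher's exact test, Cohen's kappa, Bland-Altman agreement,
    paired t-tests). Reads and writes CT slices as NIfTI-1 and minimal
    single-frame DICOM.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
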