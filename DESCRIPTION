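Package: vitalcam
Title: Contactless Vital-Sign Estimation from Thermal and Tri-Channel Camera Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates skin temperature, respiratory rate and heart rate from
    camera data without subject contact. Skin temperature is read from a
    forehead region of interest in thermal frames and compensated for ambient
    temperature and subject distance without a black-body reference, with the
    distance itself inferred from the pose-corrected face bounding-box
    diagonal. Respiratory rate is extracted from the periodic temperature
    oscillation of the facemask region by peak-to-peak and FFT estimators.
    Heart rate is recovered from tri-channel (630/532/465 nm) forehead
    reflectance traces by the plane-orthogonal-to-skin (POS)
    photoplethysmography method. Includes screening for fever, tachypnea and
    tachycardia, a synthetic scene generator with known ground truth for
    end-to-end validation, and a command-line screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
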