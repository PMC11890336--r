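Package: sonopath
Title: Registration of Resected-Specimen Ultrasound to Histopathology with
    Margin Measurement and Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers 2D ultrasound slices of resected tumor specimens to
    their corresponding histopathology whole-slide images using corresponding
    landmark point lists (circumferential landmarks plus up to three fiducial
    markers), validates each candidate transform by leave-one-out target
    registration error, transfers the histopathological tumor annotation into
    the ultrasound frame, measures resection margins (cranial, deep, caudal)
    and tumor thickness per annotation source, and quantifies agreement
    (Bland-Altman limits of agreement) and Spearman correlation between
    ultrasound- and histology-based measurements. Includes segmentation
    evaluation metrics (Dice, average surface distance, 95th-percentile
    Hausdorff distance) and a synthetic phantom generator with known ground
    truth for end-to-end validation. Reads and writes NRRD, NIfTI-1,
    3D Slicer markups (FCSV and JSON), PNG/TIFF rasters and CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
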