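Package: fetalbiom
Title: Fetal Biometry and Amniotic Fluid Assessment from Ultrasound Cine-Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline turning segmented fetal ultrasound
    cine-loops into clinical biometry: head and abdominal circumference by
    direct least-squares ellipse fitting, biparietal diameter, femur length
    from the minimum-area rotated bounding box, single-deepest-pocket
    amniotic fluid depth, Hadlock estimated fetal weight, Intergrowth
    gestational age, and amniotic-fluid-volume categories. Candidate frames
    are scored against ISUOG-derived standard-plane quality criteria and the
    best plane per loop is selected by a composite score. Includes a
    synthetic phantom generator with exact ground truth, reconstruction of
    burned-in caliper/ellipse annotations, and the agreement statistics used
    for method comparison (mean absolute error, percentage Bland-Altman
    limits of agreement, intraclass correlation, paired Wilcoxon,
    sensitivity/specificity, Dice/IoU).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    pracma,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
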