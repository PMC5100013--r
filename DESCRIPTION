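Package: rootkin
Title: Root Growth Kinematics and Zone-Resolved Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinematic analysis of growing root apices from time-lapse image
    sequences, and classification of zone-preferred and osmotic-stress-responsive
    genes from expression tables. Velocity profiles are recovered by particle
    image velocimetry with subpixel cross-correlation, interpolated with a cubic
    smoothing spline, and differentiated to the elemental elongation rate (EER)
    profile; growth traits (growth rate, maximal EER and its abscissa, growth
    zone length, division zone length from infrared brightness, cell production
    rate by meristem flux) are extracted and compared across time points with
    repeated-measures ANOVA and paired t-tests. A synthetic-data module
    generates root phantoms and replicated FPKM tables with known ground truth
    so that every stage of the pipeline is verifiable. Differential expression
    uses fold-change, t-test and false-discovery-rate thresholds on FPKM tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
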