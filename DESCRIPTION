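Package: roptode
Title: Ratiometric Oxygen Optode Imaging and Reactor Oxygen Consumption Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes time-lapse RGB images of ratiometric oxygen-sensing
    optode disks into dissolved-oxygen time series and oxygen-consumption
    rates for small batch-reactor metabolism experiments. Fits and inverts
    the modified Stern-Volmer quenching response per disk, extracts circular
    region-of-interest channel statistics from PNG/TIFF frames, converts
    between percent air saturation and mg/L with a Benson-Krause solubility
    model including pressure scaling and a salinity correction, estimates
    whole-tube oxygen permeability from sealed-reactor reaeration curves and
    corrects consumption rates for diffusive influx, computes limit of
    detection and quantification metrology from calibration noise and slope,
    and segments oxygen decline curves into first-order, zero-order and
    anoxic phases with robust outlier masking. A synthetic-campaign
    simulator renders optode frames from configured kinetic truth so the
    full pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
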