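Package: clathrakit
Title: Thermokinetic and Spectral Characterization of Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize cyclodextrin host-guest inclusion complexes
    (clathrates) from thermogravimetric and spectroscopic evidence. Provides a
    forward simulator of nth-order Arrhenius mass loss under linear heating with
    known ground-truth parameters; readers and Savitzky-Golay differentiation for
    thermogravimetric (TG/DTG) curves with multi-step segmentation; four
    model-fitting kinetic estimators of activation energy, reaction order and
    pre-exponential factor (Freeman-Carroll, Sharp-Wentworth, Achar,
    Coats-Redfern) with a cross-method consensus check; NMR chemical-shift
    displacement (delta-delta) analysis ranking host cavity protons; FTIR band
    matching between free host and complex peak lists; and a pipeline assembling
    all evidence streams into a single complexation report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
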