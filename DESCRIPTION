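Package: dipshiftr
Title: Order Parameters of Membrane Proteins from DIPSHIFT Solid-State NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and least-squares fitting of DIPSHIFT 1H-13C dipolar
    dephasing curves under magic-angle spinning to extract molecular order
    parameters of membrane proteins, together with chemical-shift-region
    quantification of secondary structure from 1D/2D spectra and static 31P
    powder-lineshape analysis of the isotropic lipid fraction. Includes a
    synthetic-data generator that emulates cross-polarization dynamic bias,
    Gaussian-peak spectra and two-component 31P lineshapes so that every
    analysis stage is testable without experimental spectra.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
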