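Package: paintability
Title: Absolute Addressability of DNA Origami from DNA-PAINT Localizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies incorporation and accessibility ("addressability") of
    individual docking strands in DNA origami nanostructures from DNA-PAINT
    single-molecule localization data. Provides a kinetic DNA-PAINT simulator
    with per-site ground truth, origami site-pattern design tools (20-nm grid,
    3/6 binding-site pair, an 18-variant rectangle library), template rendering
    and alignment by stepwise rotational cross-correlation, per-site
    localization counting with Gaussian-fit half-maximum thresholding,
    detection-efficiency statistics with bootstrap errors and false-positive
    rates, two-color coincidence analysis decoupling incorporation from
    accessibility, and a Michaelis-Menten fit of detection versus staple
    excess.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
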