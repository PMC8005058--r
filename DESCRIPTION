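Package: amzitwin
Title: Digital Twin of a Multiplexed Asymmetric Mach-Zehnder Interferometer Biosensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the full signal chain of a swept-wavelength, multiplexed
    asymmetric Mach-Zehnder interferometer (aMZI) biosensor for blood-borne
    protein biomarkers: analyte binding kinetics on functionalized waveguide
    surfaces, effective-index changes, per-cycle interferogram acquisition with
    an amplitude/spectral/temperature noise budget, Fourier phase demodulation
    into sensorgrams, differential referencing, and the standard refractometric
    performance figures (free spectral range, sensitivity, resolution, limit of
    detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
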