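Package: specklerheo
Title: Wideband Passive Microrheology from Laser Speckle Time Series
Version: 0.1.0
Authors@R: person("Speckle", "Rheology Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts laser-speckle intensity time series into wideband
    frequency-dependent viscoelastic spectra G'(omega), G''(omega) and
    |G*(omega)| via the contrast-normalized intensity autocorrelation g2(t),
    an empirical diffusing-wave-spectroscopy inversion to the probe mean
    square displacement calibrated by Monte Carlo photon transport, and an
    algebraic generalized Stokes-Einstein relation. Segments the resulting
    spectra into viscoelastic regimes and extracts spectroscopic fingerprint
    parameters (transition frequencies, elastic plateau moduli, power-law
    exponents). Includes a forward simulator that generates GSER-consistent
    mean square displacements, synthetic correlation curves, and full
    synthetic speckle movies from prescribed viscoelastic models so the
    entire chain is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
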