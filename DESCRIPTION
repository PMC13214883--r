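Package: ramanticipate
Title: Anticipation of In-Line Raman Spectra for Bioprocess Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forecasts future in-line Raman spectra of a running cell-culture
    batch from a short moving window of recent acquisitions.  Spectra in the
    window are projected onto two principal components; the first score is
    extrapolated linearly against time, the second against the first, and the
    extrapolated scores are back-projected to the wavenumber axis to give an
    anticipated spectrum.  Includes a naive last-spectrum baseline, a
    cosine-similarity evaluation framework built on the signed time offset
    between a prediction and its most similar actual spectrum, optional
    Savitzky-Golay second-derivative detrending, a synthetic
    fermentation-spectra generator with known latent dynamics and ground-truth
    optical density, and a ridge-regression demonstrator that feeds
    anticipated spectra to a spectrum-to-biomass model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    signal,
    jsonlite,
    optparse,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
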