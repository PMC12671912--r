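Package: emarate
Title: Spectral Selection of Sampling Rates for Ecological Momentary Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for choosing how often to sample ecological momentary
    assessment (EMA) items such as daily mood ratings. Implements per-person
    Welch power spectral density estimation, normalized cumulative power
    curves, objective knee-point detection (Kneedle, second-derivative and
    threshold criteria), and Nyquist-doubled sampling-rate recommendations,
    together with a synthetic EMA cohort generator, inclusion/gap filtering
    with linear interpolation, frequency-wise variance comparisons between
    cohorts, and a stepwise personalized sampling protocol with
    reconstruction-based rate validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
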