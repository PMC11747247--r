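Package: behavosc
Title: Spectral Analysis of Behavioural Oscillations with Surrogate-Based
    Cluster Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting rhythmic fluctuations in dense-sampled
    behavioural accuracy time courses. Trial-level records from a
    dense-sampling psychophysics paradigm are aggregated into per-subject,
    per-session accuracy-by-delay series, polynomially detrended, and
    transformed into zero-padded, single-taper power spectra. Observed
    spectra are tested against three surrogate-data nulls (time shuffling,
    binomial response resampling, and a fitted first-order autoregressive
    model) with a cluster-based permutation test on per-frequency paired
    t-statistics. A synthetic-experiment generator provides logistic
    observer models, the two adaptive staircases used to calibrate
    subliminal contrast and threshold stimulus onset asynchrony, and full
    trial-level datasets with controllable oscillatory accuracy modulation,
    so the whole pipeline can be exercised and calibrated without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
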