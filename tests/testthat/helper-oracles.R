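# Independent brute-force oracles and small fixtures used across tests.

# Naive O(N^2) DFT power at the requested frequencies: the padded, tapered
# series is transformed term by term, independently of stats::fft.
naive_dft_power <- function(y_padded, sample_rate_hz, frequencies_hz) {
  n <- length(y_padded)
  t_idx <- 0:(n - 1)
  vapply(frequencies_hz, function(f) {
    w <- -2i * pi * f / sample_rate_hz * t_idx
    Mod(sum(y_padded * exp(w)))^2
  }, numeric(1))
}

# First Slepian (dpss) taper for 19 samples at 60 Hz with 3 Hz half-bandwidth
# smoothing (time-half-bandwidth 0.95), unit RMS; reference values computed
# with an independent eigenvector implementation (scipy.signal.windows.dpss).
dpss19_reference <- c(
  0.425601362674, 0.563309203570, 0.705136103209, 0.845138920383,
  0.977131211645, 1.095047321824, 1.193308567299, 1.267166202284,
  1.312997173335, 1.328531792981, 1.312997173335, 1.267166202284,
  1.193308567299, 1.095047321824, 0.977131211645, 0.845138920383,
  0.705136103209, 0.563309203570, 0.425601362674
)

# raw accuracy series on the default 19-frame grid
make_series <- function(accuracy, subject = "S01", session = 1L,
                        n_trials = rep(20L, length(accuracy)),
                        delays_ms = default_delay_grid(
                          n_delays = length(accuracy)
                        )) {
  delay_series(
    subject = subject, session = session, delays_ms = delays_ms,
    accuracy = accuracy, n_trials = n_trials
  )
}

# deterministic cosine accuracy profile on the default grid
cosine_accuracy <- function(freq_hz, amplitude, base = 0.5, phase = 0,
                            delays_ms = default_delay_grid()) {
  base + amplitude * cos(2 * pi * freq_hz * delays_ms / 1000 + phase)
}

# observers reused across tests
always_no_observer <- function() observer_model(contrast_threshold = 100)
always_yes_observer <- function() {
  observer_model(contrast_threshold = -1, contrast_slope = 1e6, lapse_rate = 0)
}
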