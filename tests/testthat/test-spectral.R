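test_that("taper construction matches closed forms and references", {
  # no taper: all ones (already unit RMS)
  expect_equal(make_taper(7, 60, taper_spec("none")), rep(1, 7))

  # Hann, n = 4, symmetric convention: proportional to [0, .75, .75, 0]
  w <- make_taper(4, 60, taper_spec("hann"))
  expect_equal(w / max(w), c(0, 1, 1, 0))
  expect_equal(w, c(0, 0.75, 0.75, 0) / sqrt(mean(c(0, 0.75, 0.75, 0)^2)))
  expect_equal(sqrt(mean(w^2)), 1)

  # single dpss, 19 samples at 60 Hz, 3 Hz smoothing: NW = 0.95; symmetric,
  # unimodal, and equal to an independent eigenvector implementation
  w <- make_taper(19, 60, taper_spec("dpss_single", smoothing_hz = 3))
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-12)
  expect_equal(w, rev(w), tolerance = 1e-9)
  expect_equal(which.max(w), 10L)
  expect_true(all(diff(w[1:10]) > 0))
  expect_equal(w, dpss19_reference, tolerance = 1e-8)

  expect_error(make_taper(19, 60, taper_spec("dpss_single", -1)))
})

test_that("spectrum of an all-zero series is zero everywhere on the 1-29 Hz grid", {
  s <- make_series(rep(0.5, 19))
  sp <- compute_power_spectrum(detrend_series(s))
  expect_equal(sp$frequencies_hz, 1:29, tolerance = 1e-9)
  expect_equal(sp$power, rep(0, 29))
})

test_that("a 10 Hz cosine peaks at the 10 Hz bin", {
  s <- make_series(cosine_accuracy(10, 0.2))
  sp <- compute_power_spectrum(detrend_series(s), taper = taper_spec("none"))
  expect_equal(sp$frequencies_hz[which.max(sp$power)], 10, tolerance = 1e-9)
})

test_that("FFT power equals the naive DFT oracle for many lengths and tapers", {
  set.seed(301)
  for (n in c(4, 5, 19, 31, 64)) {
    for (kind in c("none", "hann", "dpss_single")) {
      delays <- default_delay_grid(first_frame = 10, n_delays = n)
      s <- make_series(runif(n, 0.3, 0.7), delays_ms = delays,
                       n_trials = rep(20L, n))
      det <- detrend_series(s)
      tp <- taper_spec(kind)
      pad <- 2 # seconds; 120-sample grid holds every tested length
      sp <- compute_power_spectrum(det, pad_seconds = pad, taper = tp)
      w <- make_taper(n, 60, tp)
      y_pad <- c(det$accuracy * w, rep(0, round(pad * 60) - n))
      oracle <- naive_dft_power(y_pad, 60, sp$frequencies_hz)
      expect_equal(sp$power, oracle, tolerance = 1e-10)
    }
  }
})

test_that("power is invariant to time reversal and quadratic in amplitude", {
  set.seed(302)
  acc <- runif(19, 0.3, 0.7)
  sp <- compute_power_spectrum(detrend_series(make_series(acc)))
  sp_rev <- compute_power_spectrum(detrend_series(make_series(rev(acc))))
  expect_equal(sp$power, sp_rev$power, tolerance = 1e-10)

  centred <- acc - mean(acc)
  doubled <- 0.5 + 2 * centred
  sp2 <- compute_power_spectrum(detrend_series(make_series(doubled)))
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-9)
})

test_that("sampling geometry gives 60 Hz rate, 30 Hz Nyquist, 1 Hz bins", {
  grid <- default_delay_grid()
  fs <- sample_rate_hz(grid)
  expect_equal(fs, 60)
  expect_equal(fs / 2, 30)
  sp <- compute_power_spectrum(detrend_series(make_series(runif(19))))
  expect_equal(sp$frequencies_hz, 1:29, tolerance = 1e-9)
  expect_equal(diff(sp$frequencies_hz), rep(1, 28), tolerance = 1e-9)
})

test_that("spectral preconditions are enforced", {
  s <- make_series(runif(19, 0.4, 0.6))
  expect_error(compute_power_spectrum(s), "detrended")
  det <- detrend_series(s)
  expect_error(compute_power_spectrum(det, pad_seconds = 0.1), "pad")
})

test_that("spectra average element-wise with grid checking", {
  mk <- function(p, subject = "S01", session = 1) {
    behavosc:::new_power_spectrum(
      subject, session, frequencies_hz = c(1, 2), power = p,
      pad_seconds = 1, taper = taper_spec("none")
    )
  }
  a <- mk(c(2, 4), session = 1)
  b <- mk(c(4, 8), session = 2)
  avg <- average_spectra(list(a, b), over = "sessions")
  expect_equal(avg$power, c(3, 6))
  one <- average_spectra(list(a), over = "sessions")
  expect_equal(one$power, a$power)
  same <- average_spectra(list(a, a, a), over = "sessions")
  expect_equal(same$power, a$power)
  bad <- mk(c(1, 1))
  bad$frequencies_hz <- c(1, 3)
  expect_error(average_spectra(list(a, bad)), "grids")
})

test_that("the full-cycle frequency bound for a 288 ms window is 3.47 Hz", {
  expect_equal(round(min_full_cycle_frequency(0.288), 2), 3.47)
})
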