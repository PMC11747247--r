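test_that("surrogate machinery shares the observed pipeline's spectral path", {
  set.seed(401)
  s <- make_series(runif(19, 0.35, 0.65))
  observed <- compute_power_spectrum(detrend_series(s))
  pc <- behavosc:::surrogate_power(
    matrix(s$accuracy, ncol = 1), s$delays_ms,
    detrend_order = 1, pad_seconds = 1, taper = taper_spec(),
    fmin_hz = 1, fmax_hz = 29
  )
  expect_equal(drop(pc$power), observed$power, tolerance = 1e-12)
  expect_equal(pc$frequencies_hz, observed$frequencies_hz)
})

test_that("time shuffling permutes the raw values and spares nothing else", {
  set.seed(402)
  acc <- runif(19, 0.3, 0.7)
  Y <- behavosc:::shuffle_matrix(acc, 50)
  for (j in seq_len(ncol(Y))) {
    expect_equal(sort(Y[, j]), sort(acc))
  }
  # constant series: every permutation identical to the observed series
  s0 <- make_series(rep(0.55, 19))
  reps <- surrogate_time_shuffle(s0, n_reps = 8, seed = 1)
  obs <- compute_power_spectrum(detrend_series(s0))
  for (i in 1:8) expect_equal(unname(reps$power[i, ]), obs$power)
  # a detrended series is refused: raw values are what gets shuffled
  expect_error(surrogate_time_shuffle(detrend_series(make_series(acc))),
               "raw")
})

test_that("shuffling destroys the power of a strong rhythmic component", {
  s <- make_series(cosine_accuracy(11, 0.25))
  obs <- compute_power_spectrum(detrend_series(s))
  reps <- surrogate_time_shuffle(s, n_reps = 500, seed = 403)
  bin11 <- which(abs(reps$frequencies_hz - 11) < 1e-6)
  expect_lt(mean(reps$power[, bin11]), obs$power[bin11])
})

test_that("random-accuracy surrogates match their binomial construction", {
  nt <- rep(20L, 19)
  set.seed(404)
  A <- behavosc:::random_accuracy_matrix(nt, 1e4, m = 0.5, "offset")
  # per-delay SD is sqrt(0.25 / 20) ~ 0.1118 (within 3%)
  sds <- apply(A, 1, sd)
  expect_true(all(abs(sds - sqrt(0.25 / 20)) / sqrt(0.25 / 20) < 0.03))
  # offset centres every delay at the session mean
  B <- behavosc:::random_accuracy_matrix(nt, 1e4, m = 0.62, "offset")
  expect_true(all(abs(rowMeans(B) - 0.62) < 3 * sqrt(0.25 / 20) / 100))

  s <- make_series(runif(19, 0.4, 0.6))
  expect_error(
    surrogate_random_accuracy(s, 10, session_mean_accuracy = 1.2),
    "\\[0, 1\\]"
  )
})

test_that("random-accuracy surrogate power vanishes as trial counts grow", {
  s_small <- make_series(rep(0.5, 19), n_trials = rep(20L, 19))
  s_big <- make_series(rep(0.5, 19), n_trials = rep(100000L, 19))
  small <- surrogate_random_accuracy(s_small, n_reps = 200, seed = 405)
  big <- surrogate_random_accuracy(s_big, n_reps = 200, seed = 405)
  expect_lt(mean(big$power), mean(small$power) / 1000)
  expect_lt(mean(big$power), 1e-3)
})

test_that("AR(1) fitting recovers known coefficients", {
  set.seed(406)
  n <- 1000
  # phi = 0.6 simulation
  x <- as.numeric(arima.sim(list(ar = 0.6), n = n, sd = 0.1))
  f <- fit_ar1(x)
  expect_lt(abs(f$phi - 0.6), 0.1)
  # white noise: phi near 0
  w <- rnorm(n)
  fw <- fit_ar1(w)
  expect_lt(abs(fw$phi), 0.1)
  expect_lt(abs(fw$resid_sd - 1), 0.1)
  # adding a constant is absorbed by c, phi untouched (lag regression form)
  f1 <- fit_ar1(x, method = "css")
  f2 <- fit_ar1(x + 5, method = "css")
  expect_lt(abs(f1$phi - f2$phi), 1e-6)
  # degenerate input
  expect_error(fit_ar1(rep(0.5, 19)), "degenerate")
})

test_that("AR surrogates have the right spectral shape", {
  s <- make_series(runif(19, 0.4, 0.6))
  # zero innovation, phi 0: constant process, zero power after demeaning
  silent <- surrogate_ar(ar_fit(c = 0.3, phi = 0, resid_sd = 0), s,
                         n_reps = 5, seed = 407)
  expect_equal(max(silent$power), 0)
  # white noise: expected spectrum matches the closed form
  # E[P(f)] = sigma^2 * || conj(f_f) * w  %*%  Q ||^2  (detrend projector Q
  # shapes bins below ~5 Hz; the rest of the band is flat)
  white <- surrogate_ar(ar_fit(c = 0, phi = 0, resid_sd = 0.1), s,
                        n_reps = 4000, seed = 408)
  mp <- colMeans(white$power)
  n <- 19
  Q <- behavosc:::residual_projector(n, 1)
  w <- make_taper(n, 60, taper_spec())
  expected <- vapply(white$frequencies_hz, function(f) {
    a <- (exp(-2i * pi * f / 60 * (0:(n - 1))) * w) %*% Q
    0.1^2 * sum(Mod(a)^2)
  }, numeric(1))
  expect_equal(mp, expected, tolerance = 0.05)
  hi <- white$frequencies_hz >= 5
  slope <- coef(lm(mp[hi] ~ white$frequencies_hz[hi]))[2]
  expect_lt(abs(slope) * 24 / mean(mp[hi]), 0.05) # flat above 5 Hz
  # phi = 0.7: power concentrated at low frequencies, decreasing with f
  red <- surrogate_ar(ar_fit(c = 0, phi = 0.7, resid_sd = 0.1), s,
                      n_reps = 2000, seed = 409)
  rho <- cor(red$frequencies_hz, colMeans(red$power), method = "spearman")
  expect_lt(rho, -0.9)
  # stationarity guard
  expect_error(surrogate_ar(ar_fit(0, 1, 0.1), s, 5), "onstationary")
})

test_that("surrogate ensembles are reproducible given a seed", {
  s <- make_series(runif(19, 0.4, 0.6))
  for (gen in list(
    function(seed) surrogate_time_shuffle(s, 20, seed = seed),
    function(seed) surrogate_random_accuracy(s, 20, seed = seed),
    function(seed) surrogate_ar(ar_fit(0, 0.4, 0.1), s, 20, seed = seed)
  )) {
    expect_identical(gen(99), gen(99))
  }
})

test_that("reduction takes medians within session, means across sessions", {
  mk_reps <- function(power, session) {
    behavosc:::new_surrogate_reps(
      subject = "S01", session = session, method = "time_shuffle",
      frequencies_hz = seq_len(ncol(power)), power = power,
      n_reps = nrow(power)
    )
  }
  # single repetition, single session: identity
  one <- mk_reps(matrix(c(3, 7), 1), 1)
  expect_equal(reduce_surrogates(one)$power, c(3, 7))
  # median robustness: {1, 2, 100} -> 2
  rob <- mk_reps(matrix(c(1, 2, 100), 3, 1), 1)
  expect_equal(reduce_surrogates(rob)$power, 2)
  expect_equal(reduce_surrogates(rob, reduce = "mean")$power, mean(c(1, 2, 100)))
  # sessions [2] and [4] -> [3]
  two <- list(mk_reps(matrix(2), 1), mk_reps(matrix(4), 2))
  expect_equal(reduce_surrogates(two)$power, 3)
})

test_that("observed and mean-reduced surrogate power overlap under the null,
           while median reduction sits below the observed level", {
  set.seed(410)
  n_sub <- 50
  obs <- sur_med <- sur_mean <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    acc <- rbinom(19, 20, 0.5) / 20
    s <- make_series(acc)
    obs[i] <- mean(compute_power_spectrum(detrend_series(s))$power)
    reps <- surrogate_random_accuracy(s, n_reps = 200)
    sur_med[i] <- mean(reduce_surrogates(reps)$power)
    sur_mean[i] <- mean(reduce_surrogates(reps, reduce = "mean")$power)
  }
  # unbiased reduction: distributions overlap (location test n.s. at 1%)
  expect_gt(wilcox.test(obs, sur_mean)$p.value, 0.01)
  # median reduction: systematic downward shift of the surrogate level
  expect_lt(wilcox.test(obs, sur_med, alternative = "greater")$p.value, 0.01)
})
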