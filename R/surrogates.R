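#' @title Surrogate-data spectra
#' @description Three surrogate constructions provide null distributions of
#'   spectral power against which the observed accuracy spectrum is tested:
#'   shuffling the raw accuracy values in time (destroys temporal order,
#'   keeps the value multiset), redrawing responses as fair coin flips with a
#'   per-session performance offset (keeps trial-count noise, destroys
#'   everything else), and simulating a first-order autoregressive process
#'   fitted to the detrended series (keeps lag-one autocorrelation). Every
#'   repetition runs through the identical detrend/taper/pad/FFT path as the
#'   observed data.
#' @name surrogates
NULL

# columns are independent uniform permutations of acc
shuffle_matrix <- function(acc, n_reps) {
  vapply(seq_len(n_reps), function(i) sample(acc), numeric(length(acc)))
}

# columns are surrogate accuracy series: per delay, the mean of n_trials
# Bernoulli draws, either fair coin + performance offset or Bernoulli(m)
random_accuracy_matrix <- function(n_trials, n_reps, m, bernoulli) {
  nd <- length(n_trials)
  if (bernoulli == "offset") {
    matrix(stats::rbinom(nd * n_reps, size = n_trials, prob = 0.5), nd) /
      n_trials + (m - 0.5)
  } else {
    matrix(stats::rbinom(nd * n_reps, size = n_trials, prob = m), nd) /
      n_trials
  }
}

# Shared downstream path for all surrogate methods: detrend each column of
# Y exactly as detrend_series() does, then the same power_core() used by
# compute_power_spectrum().
surrogate_power <- function(Y, delays_ms, detrend_order, pad_seconds, taper,
                            fmin_hz, fmax_hz) {
  Q <- residual_projector(nrow(Y), detrend_order)
  R <- Q %*% Y
  R <- sweep(R, 2, colMeans(R)) # exact demeaning against round-off
  fs <- sample_rate_hz(delays_ms)
  w <- make_taper(nrow(Y), fs, taper)
  power_core(R, fs, pad_seconds, w, fmin_hz, fmax_hz)
}

new_surrogate_reps <- function(subject, session, method, frequencies_hz,
                               power, n_reps) {
  structure(
    list(
      subject = subject, session = session, method = method,
      frequencies_hz = frequencies_hz, power = power, n_reps = n_reps
    ),
    class = "surrogate_reps"
  )
}

#' @export
print.surrogate_reps <- function(x, ...) {
  cat(sprintf(
    "<surrogate_reps> %s: subject %s, session %s, %d repetitions x %d bins\n",
    x$method, x$subject, x$session, x$n_reps, length(x$frequencies_hz)
  ))
  invisible(x)
}

#' Time-shuffle surrogate spectra
#'
#' Each repetition permutes the raw (pre-detrend) accuracy values uniformly
#' across delays, then detrends, demeans and computes the power spectrum
#' with the same settings as the observed pipeline. Shuffling raw values and
#' detrending per repetition matches the convention that the trend is part
#' of what a permutation may destroy.
#'
#' @param series a raw (not yet detrended) [delay_series()].
#' @param n_reps number of repetitions (default 1000).
#' @param detrend_order polynomial detrend order, 1 or 2.
#' @param pad_seconds,taper,fmin_hz,fmax_hz spectral settings, as in
#'   [compute_power_spectrum()].
#' @param seed optional integer seed.
#' @return A `surrogate_reps` object: per-repetition power in an
#'   `n_reps x n_frequencies` matrix.
#' @export
surrogate_time_shuffle <- function(series, n_reps = 1000L,
                                   detrend_order = 1L, pad_seconds = 1,
                                   taper = taper_spec(),
                                   fmin_hz = 1, fmax_hz = 29,
                                   seed = NULL) {
  stopifnot(inherits(series, "delay_series"))
  if (!identical(series$detrend_order, "none")) {
    stop_invalid("time shuffling permutes raw accuracies; pass the ",
                 "un-detrended series")
  }
  if (!is_scalar_number(n_reps) || n_reps < 1) {
    stop_invalid("n_reps must be at least 1")
  }
  with_seed(seed, {
    Y <- shuffle_matrix(series$accuracy, n_reps)
    pc <- surrogate_power(Y, series$delays_ms, detrend_order, pad_seconds,
                          taper, fmin_hz, fmax_hz)
    new_surrogate_reps(series$subject, series$session, "time_shuffle",
                       pc$frequencies_hz, t(pc$power), as.integer(n_reps))
  })
}

#' Random-accuracy (binomial) surrogate spectra
#'
#' Each repetition redraws, at every delay, as many fair Bernoulli responses
#' as the observed trial count, averages them into a surrogate accuracy, and
#' adds an offset equal to the session's mean accuracy minus 0.5 so the
#' surrogate matches the observer's overall performance level
#' (`bernoulli = "offset"`, the default). The alternative parameterisation
#' `bernoulli = "mean"` draws Bernoulli(session mean) responses directly.
#' Each repetition is then detrended, demeaned and Fourier-transformed with
#' the observed pipeline's settings.
#'
#' @param series a raw [delay_series()]; supplies the per-delay trial counts
#'   and (unless overridden) the session mean accuracy.
#' @param session_mean_accuracy overall threshold-SOA accuracy of the session
#'   (default: trial-weighted mean of `series$accuracy`).
#' @param bernoulli `"offset"` (fair coin + offset) or `"mean"`.
#' @inheritParams surrogate_time_shuffle
#' @return A `surrogate_reps` object.
#' @export
surrogate_random_accuracy <- function(series, n_reps = 1000L,
                                      session_mean_accuracy = NULL,
                                      bernoulli = c("offset", "mean"),
                                      detrend_order = 1L, pad_seconds = 1,
                                      taper = taper_spec(),
                                      fmin_hz = 1, fmax_hz = 29,
                                      seed = NULL) {
  stopifnot(inherits(series, "delay_series"))
  bernoulli <- match.arg(bernoulli)
  if (!identical(series$detrend_order, "none")) {
    stop_invalid("pass the un-detrended series")
  }
  if (!is_scalar_number(n_reps) || n_reps < 1) {
    stop_invalid("n_reps must be at least 1")
  }
  m <- session_mean_accuracy %||%
    stats::weighted.mean(series$accuracy, series$n_trials)
  if (m < 0 || m > 1) {
    stop_invalid("session_mean_accuracy must lie in [0, 1]")
  }
  with_seed(seed, {
    Y <- random_accuracy_matrix(series$n_trials, n_reps, m, bernoulli)
    pc <- surrogate_power(Y, series$delays_ms, detrend_order, pad_seconds,
                          taper, fmin_hz, fmax_hz)
    new_surrogate_reps(series$subject, series$session, "random_accuracy",
                       pc$frequencies_hz, t(pc$power), as.integer(n_reps))
  })
}

#' Construct an AR(1) model specification
#'
#' Builds an `ar_fit` object directly, e.g. to simulate surrogates from known
#' parameters rather than a fitted model.
#'
#' @param c constant term (accuracy units).
#' @param phi autoregression coefficient.
#' @param resid_sd innovation standard deviation, `>= 0`.
#' @param n_obs nominal number of observations (default `NA`).
#' @return An object of class `ar_fit`.
#' @export
ar_fit <- function(c, phi, resid_sd, n_obs = NA_integer_) {
  stopifnot(
    is_scalar_number(c), is_scalar_number(phi),
    is_scalar_number(resid_sd), resid_sd >= 0
  )
  structure(
    list(c = c, phi = phi, resid_sd = resid_sd, n_obs = n_obs,
         method = "specified"),
    class = "ar_fit"
  )
}

#' Fit a first-order autoregressive model to a detrended series
#'
#' Estimates the AR(1) model `X_t = c + phi * X_{t-1} + eps_t` on the
#' detrended accuracy series. The default is the Gaussian maximum-likelihood
#' fit of [stats::arima()] with `order = c(1, 0, 0)`; if that fails on a
#' degenerate short series, a conditional-least-squares fallback (ordinary
#' regression of `X_t` on `X_{t-1}`) is used. The innovation scale is the
#' residual standard deviation.
#'
#' @param x a detrended [delay_series()] or a numeric vector (length >= 3).
#' @param method `"ml"` (default) or `"css"` for the lag-regression fit.
#' @return An object of class `ar_fit`: `c`, `phi`, `resid_sd`, `n_obs`,
#'   `method`.
#' @export
fit_ar1 <- function(x, method = c("ml", "css")) {
  method <- match.arg(method)
  if (inherits(x, "delay_series")) {
    if (identical(x$detrend_order, "none")) {
      stop_invalid("fit_ar1 expects the detrended series")
    }
    x <- x$accuracy
  }
  stopifnot(is.numeric(x))
  if (length(x) < 3) stop_invalid("need at least 3 points to fit AR(1)")
  if (stats::sd(x) == 0) {
    stop_invalid("degenerate fit: input series is constant")
  }
  fit <- NULL
  if (method == "ml") {
    fit <- tryCatch(
      {
        f <- stats::arima(x, order = c(1, 0, 0), method = "ML")
        mu <- unname(f$coef["intercept"])
        phi <- unname(f$coef["ar1"])
        list(c = mu * (1 - phi), phi = phi,
             resid_sd = sqrt(max(f$sigma2, 0)), method = "ml")
      },
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    # conditional least squares: regress X_t on X_{t-1}
    x1 <- x[-length(x)]
    x2 <- x[-1]
    if (stats::sd(x1) == 0) stop_invalid("degenerate fit: no lag variance")
    phi <- stats::cov(x1, x2) / stats::var(x1)
    cc <- mean(x2) - phi * mean(x1)
    r <- x2 - cc - phi * x1
    df <- max(length(r) - 2, 1)
    fit <- list(c = cc, phi = phi,
                resid_sd = sqrt(sum(r^2) / df), method = "css")
  }
  structure(
    list(c = fit$c, phi = fit$phi, resid_sd = fit$resid_sd,
         n_obs = length(x), method = fit$method),
    class = "ar_fit"
  )
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf(
    "<ar_fit> X_t = %.4g + %.3f X_[t-1] + eps,  sd(eps) = %.4g  (n = %d, %s)\n",
    x$c, x$phi, x$resid_sd, x$n_obs, x$method
  ))
  invisible(x)
}

#' Autoregressive surrogate spectra
#'
#' Each repetition simulates the fitted AR(1) process (Gaussian innovations
#' with the fitted residual standard deviation, `burn_in` initial samples
#' discarded) to the original series length, then detrends, demeans and
#' Fourier-transforms it with the observed pipeline's settings.
#'
#' @param fit an [fit_ar1()] result; requires `|phi| < 1` (stationarity).
#' @param series the [delay_series()] whose length and delay grid the
#'   surrogates must match (raw or detrended; only geometry is used).
#' @param burn_in discarded initial samples per repetition (default 100).
#' @inheritParams surrogate_time_shuffle
#' @return A `surrogate_reps` object.
#' @export
surrogate_ar <- function(fit, series, n_reps = 1000L, burn_in = 100L,
                         detrend_order = 1L, pad_seconds = 1,
                         taper = taper_spec(), fmin_hz = 1, fmax_hz = 29,
                         seed = NULL) {
  stopifnot(inherits(fit, "ar_fit"), inherits(series, "delay_series"))
  if (abs(fit$phi) >= 1) {
    stop_invalid("nonstationary model: |phi| must be < 1")
  }
  if (!is_scalar_number(n_reps) || n_reps < 1) {
    stop_invalid("n_reps must be at least 1")
  }
  n <- length(series$delays_ms)
  with_seed(seed, {
    total <- n + burn_in
    X <- matrix(0, total, n_reps)
    E <- matrix(stats::rnorm(total * n_reps, sd = fit$resid_sd), total)
    x_prev <- rep(fit$c / (1 - fit$phi), n_reps) # start at process mean
    for (t in seq_len(total)) {
      x_prev <- fit$c + fit$phi * x_prev + E[t, ]
      X[t, ] <- x_prev
    }
    Y <- X[(burn_in + 1):total, , drop = FALSE]
    pc <- surrogate_power(Y, series$delays_ms, detrend_order, pad_seconds,
                          taper, fmin_hz, fmax_hz)
    new_surrogate_reps(series$subject, series$session, "ar_model",
                       pc$frequencies_hz, t(pc$power), as.integer(n_reps))
  })
}

#' Reduce surrogate repetitions to one spectrum per subject
#'
#' Within each session, the per-frequency `reduce` statistic (median by
#' convention) is taken over the repetitions; the per-session reductions are
#' then averaged across the subject's sessions, mirroring the
#' sessions-then-subjects averaging of the observed spectra.
#'
#' Note that with `reduce = "median"` the per-subject surrogate spectrum sits
#' systematically below the mean observed power under a true null, because
#' spectral power is right-skewed; `reduce = "mean"` is the unbiased
#' alternative. See the package vignette for the consequences for error
#' rates.
#'
#' @param reps a single `surrogate_reps` object or a list of them (the
#'   sessions of one subject, same method and grid).
#' @param reduce `"median"` (convention) or `"mean"`.
#' @return An object of class `surrogate_spectrum`: `subject`, `method`,
#'   `frequencies_hz`, `power`, `n_reps`.
#' @export
reduce_surrogates <- function(reps, reduce = c("median", "mean")) {
  reduce <- match.arg(reduce)
  if (inherits(reps, "surrogate_reps")) reps <- list(reps)
  stopifnot(is.list(reps), length(reps) >= 1)
  for (r in reps) stopifnot(inherits(r, "surrogate_reps"))
  if (any(vapply(reps, function(r) r$n_reps, numeric(1)) < 1)) {
    stop_invalid("zero repetitions")
  }
  grid <- reps[[1]]$frequencies_hz
  method <- reps[[1]]$method
  for (r in reps) {
    if (length(r$frequencies_hz) != length(grid) ||
        max(abs(r$frequencies_hz - grid)) > 1e-9) {
      stop_invalid("frequency grids differ across sessions")
    }
    if (!identical(r$method, method)) {
      stop_invalid("cannot reduce across surrogate methods")
    }
  }
  per_session <- matrix(vapply(reps, function(r) {
    if (reduce == "median") {
      apply(r$power, 2, stats::median)
    } else {
      colMeans(r$power)
    }
  }, numeric(length(grid))), nrow = length(grid))
  structure(
    list(
      subject = reps[[1]]$subject, method = method,
      frequencies_hz = grid, power = rowMeans(per_session),
      n_reps = reps[[1]]$n_reps, reduce = reduce
    ),
    class = "surrogate_spectrum"
  )
}

#' @export
print.surrogate_spectrum <- function(x, ...) {
  cat(sprintf(
    "<surrogate_spectrum> %s (%s over %d reps): subject %s, %d bins\n",
    x$method, x$reduce, x$n_reps, x$subject, length(x$frequencies_hz)
  ))
  invisible(x)
}
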