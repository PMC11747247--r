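#' Accuracy-by-delay series for one subject and session
#'
#' The central time-series container: accuracy at the threshold SOA as an
#' ordered function of subliminal-target delay, with per-delay trial counts.
#' Delays must be strictly increasing and evenly spaced (relative tolerance
#' 1e-9), since the downstream Fourier analysis assumes uniform sampling.
#'
#' @param subject,session identifiers.
#' @param delays_ms delays in ms before the first target image.
#' @param accuracy fraction correct per delay (in `[0, 1]` for raw series;
#'   unconstrained, mean zero, for detrended series).
#' @param n_trials trial count per delay.
#' @param detrend_order `"none"` for raw series, or the polynomial order (1
#'   or 2) already removed.
#' @return An object of class `delay_series`.
#' @export
delay_series <- function(subject, session, delays_ms, accuracy, n_trials,
                         detrend_order = "none") {
  stopifnot(
    length(subject) == 1L, length(session) == 1L,
    is.numeric(delays_ms), length(delays_ms) >= 2,
    is.numeric(accuracy), length(accuracy) == length(delays_ms),
    is.numeric(n_trials), length(n_trials) == length(delays_ms),
    all(n_trials >= 1)
  )
  d <- diff(delays_ms)
  if (any(d <= 0)) stop_invalid("delays must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
    stop_invalid("delays must be evenly spaced (relative tolerance 1e-9)")
  }
  if (identical(detrend_order, "none")) {
    if (any(accuracy < 0 | accuracy > 1)) {
      stop_invalid("raw accuracy must lie in [0, 1]")
    }
  } else {
    detrend_order <- as.integer(detrend_order)
    stopifnot(detrend_order %in% 1:2)
    if (abs(mean(accuracy)) > 1e-10) {
      stop_invalid("detrended accuracy must have mean zero (within 1e-10)")
    }
  }
  structure(
    list(
      subject = subject, session = session, delays_ms = delays_ms,
      accuracy = accuracy, n_trials = n_trials, detrend_order = detrend_order
    ),
    class = "delay_series"
  )
}

#' @export
print.delay_series <- function(x, ...) {
  cat(sprintf(
    "<delay_series> subject %s, session %s: %d delays %.1f-%.1f ms, %s\n",
    x$subject, x$session, length(x$delays_ms),
    min(x$delays_ms), max(x$delays_ms),
    if (identical(x$detrend_order, "none")) "raw accuracy"
    else sprintf("detrended (order %d)", x$detrend_order)
  ))
  invisible(x)
}

#' Sampling rate of a delay grid
#'
#' @param x a `delay_series` or a numeric vector of evenly spaced delays in
#'   ms.
#' @return Sampling rate in Hz (60 Hz for the one-frame grid).
#' @export
sample_rate_hz <- function(x) {
  delays <- if (inherits(x, "delay_series")) x$delays_ms else x
  1000 / mean(diff(delays))
}

#' Aggregate trial records into an accuracy-by-delay series
#'
#' Computes, for one subject and session, the fraction of correct responses
#' among threshold-SOA trials at each delay of the sampling grid. Control-SOA
#' and catch trials are excluded. Every grid delay must have at least one
#' threshold trial; a delay with none raises an error naming it.
#'
#' @param trials trial table as produced by [generate_experiment()] or read
#'   by [read_trials()].
#' @param subject,session identifiers selecting one subject-session block.
#' @param delay_grid_ms optional expected grid; defaults to the sorted unique
#'   delays present in the selected threshold trials.
#' @return A raw [delay_series()].
#' @export
aggregate_accuracy <- function(trials, subject, session, delay_grid_ms = NULL) {
  stopifnot(is.data.frame(trials))
  sel <- trials$subject == subject & trials$session == session &
    trials$soa_condition == "threshold"
  sub <- trials[sel & !is.na(trials$delay_ms), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_invalid(
      "no threshold-SOA trials for subject ", subject, ", session ", session
    )
  }
  grid <- delay_grid_ms %||% sort(unique(sub$delay_ms))
  idx <- match(round(sub$delay_ms, 9), round(grid, 9))
  if (anyNA(idx)) {
    stop_invalid("trials at delays outside the expected grid: ",
                 paste(unique(sub$delay_ms[is.na(idx)]), collapse = ", "))
  }
  n <- tabulate(idx, nbins = length(grid))
  if (any(n == 0)) {
    stop_invalid(
      "no threshold-SOA trials at delay(s) ",
      paste(sprintf("%.1f", grid[n == 0]), collapse = ", "), " ms"
    )
  }
  ncorr <- vapply(
    seq_along(grid),
    function(i) sum(sub$correct[idx == i]),
    numeric(1)
  )
  delay_series(
    subject = subject, session = session, delays_ms = grid,
    accuracy = ncorr / n, n_trials = n
  )
}

# Residual-maker matrix for an order-p polynomial fit on n evenly spaced
# points. The abscissa is centred and scaled to [-1, 1] for conditioning;
# because the projection spans the same column space as raw-ms polynomials,
# the residuals are identical to fitting on raw delays.
residual_projector <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  X <- outer(x, 0:order, `^`)
  diag(n) - X %*% solve(crossprod(X), t(X))
}

#' Polynomially detrend (and thereby demean) a delay series
#'
#' Replaces the accuracy values with the residuals of an ordinary
#' least-squares polynomial fit of the given order in delay. Order 1 is the
#' standard linear detrend + demean applied before spectral analysis; order 2
#' is the quadratic control analysis. The constant term is part of the fit,
#' so residuals have mean zero.
#'
#' @param series a raw [delay_series()].
#' @param order polynomial order, 1 or 2.
#' @return A detrended `delay_series` (`detrend_order` set; `n_trials`
#'   preserved).
#' @export
detrend_series <- function(series, order = 1L) {
  stopifnot(inherits(series, "delay_series"))
  if (!identical(series$detrend_order, "none")) {
    stop_invalid("series is already detrended")
  }
  order <- as.integer(order)
  if (!order %in% 1:2) stop_invalid("order must be 1 or 2")
  n <- length(series$accuracy)
  if (n < order + 2) stop_invalid("need at least order + 2 points to detrend")
  Q <- residual_projector(n, order)
  r <- drop(Q %*% series$accuracy)
  r <- r - mean(r) # exact demeaning against round-off
  delay_series(
    subject = series$subject, session = series$session,
    delays_ms = series$delays_ms, accuracy = r,
    n_trials = series$n_trials, detrend_order = order
  )
}
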