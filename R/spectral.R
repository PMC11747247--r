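#' Taper specification
#'
#' Describes the window applied to the (short) accuracy series before
#' zero-padding and the Fourier transform. The default is a single discrete
#' prolate spheroidal sequence (dpss, Slepian) taper whose half-bandwidth
#' gives a spectral smoothing of 3 Hz; this trades frequency resolution for
#' reduced leakage, which is appropriate for a 19-sample window. A Hann
#' window and no taper are available as alternatives.
#'
#' @param kind one of `"dpss_single"`, `"hann"`, `"none"`.
#' @param smoothing_hz half-bandwidth in Hz for `"dpss_single"` (default 3).
#' @return An object of class `taper_spec`.
#' @export
taper_spec <- function(kind = c("dpss_single", "hann", "none"),
                       smoothing_hz = 3) {
  kind <- match.arg(kind)
  if (kind == "dpss_single") {
    stopifnot(is_scalar_number(smoothing_hz), smoothing_hz > 0)
  }
  structure(list(kind = kind, smoothing_hz = smoothing_hz),
            class = "taper_spec")
}

# First discrete prolate spheroidal sequence of length n with
# time-half-bandwidth product nw, via the classical symmetric tridiagonal
# eigenproblem. Sign fixed so the weights sum positive; unimodal and
# symmetric for the lengths used here.
dpss_first <- function(n, nw) {
  stopifnot(n >= 2, nw > 0)
  if (nw >= n / 2) stop_invalid("time-half-bandwidth must be below n/2")
  W <- nw / n
  tt <- 0:(n - 1)
  A <- diag(((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * W))
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v
}

#' Construct taper weights
#'
#' Returns a length-`n_samples` nonnegative weight vector normalised to unit
#' root-mean-square, so that tapering leaves the broadband power scale of a
#' white series unchanged. For `"dpss_single"` the time-half-bandwidth
#' product is `n_samples / sample_rate_hz * smoothing_hz` (0.95 for 19
#' samples at 60 Hz with 3 Hz smoothing).
#'
#' @param n_samples series length, `>= 2`.
#' @param sample_rate_hz sampling rate in Hz.
#' @param spec a [taper_spec()].
#' @return Numeric weight vector of length `n_samples`.
#' @export
make_taper <- function(n_samples, sample_rate_hz, spec = taper_spec()) {
  stopifnot(
    is_scalar_number(n_samples), n_samples >= 2,
    is_scalar_number(sample_rate_hz), sample_rate_hz > 0,
    inherits(spec, "taper_spec")
  )
  n <- as.integer(n_samples)
  w <- switch(spec$kind,
    none = rep(1, n),
    hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))),
    dpss_single = {
      nw <- n / sample_rate_hz * spec$smoothing_hz
      if (nw <= 0) stop_invalid("dpss time-half-bandwidth must be positive")
      dpss_first(n, nw)
    }
  )
  w / sqrt(mean(w^2))
}

# Shared spectral core: columns of Y are detrended series; taper, zero-pad,
# FFT, squared magnitude, restrict to [fmin, fmax]. Every spectrum in the
# package -- observed or surrogate -- passes through here.
power_core <- function(Y, sample_rate_hz, pad_seconds, taper_weights,
                       fmin_hz, fmax_hz) {
  n <- nrow(Y)
  pad_n <- as.integer(round(pad_seconds * sample_rate_hz))
  if (pad_n < n) stop_invalid("pad duration shorter than the series")
  Yt <- Y * taper_weights
  Z <- rbind(Yt, matrix(0, pad_n - n, ncol(Y)))
  P <- Mod(stats::mvfft(Z))^2
  freqs <- (seq_len(pad_n) - 1) * sample_rate_hz / pad_n
  keep <- freqs >= fmin_hz - 1e-9 & freqs <= fmax_hz + 1e-9
  list(frequencies_hz = freqs[keep], power = P[keep, , drop = FALSE])
}

#' Zero-padded single-taper power spectrum of a detrended delay series
#'
#' Applies the taper to the raw-length series, zero-pads to
#' `pad_seconds` (1 s by default, giving a 1 Hz frequency grid at the 60 Hz
#' sampling rate), takes the discrete Fourier transform, and returns the
#' squared magnitude restricted to `[fmin_hz, fmax_hz]` (1-29 Hz by default,
#' i.e. everything between DC and the 30 Hz Nyquist frequency). Padding
#' zeros are never tapered: the window weights only the data samples.
#'
#' Power units are arbitrary but consistent within a run; all inference
#' compares observed against surrogate spectra computed with identical
#' settings.
#'
#' @param series a detrended [delay_series()].
#' @param pad_seconds duration to pad to, in seconds (default 1).
#' @param taper a [taper_spec()] (default single dpss, 3 Hz smoothing).
#' @param fmin_hz,fmax_hz retained frequency band in Hz (defaults 1 and 29).
#' @return An object of class `power_spectrum`: `subject`, `session`,
#'   `frequencies_hz`, `power`, `pad_seconds`, `taper`.
#' @export
compute_power_spectrum <- function(series, pad_seconds = 1,
                                   taper = taper_spec(),
                                   fmin_hz = 1, fmax_hz = 29) {
  stopifnot(inherits(series, "delay_series"))
  if (identical(series$detrend_order, "none")) {
    stop_invalid("series must be detrended before spectral analysis ",
                 "(see detrend_series)")
  }
  fs <- sample_rate_hz(series)
  w <- make_taper(length(series$accuracy), fs, taper)
  pc <- power_core(matrix(series$accuracy, ncol = 1), fs, pad_seconds, w,
                   fmin_hz, fmax_hz)
  new_power_spectrum(
    subject = series$subject, session = series$session,
    frequencies_hz = pc$frequencies_hz, power = drop(pc$power),
    pad_seconds = pad_seconds, taper = taper
  )
}

new_power_spectrum <- function(subject, session, frequencies_hz, power,
                               pad_seconds, taper) {
  stopifnot(all(power >= 0), length(power) == length(frequencies_hz))
  structure(
    list(
      subject = subject, session = session,
      frequencies_hz = frequencies_hz, power = power,
      pad_seconds = pad_seconds, taper = taper
    ),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> subject %s, session %s: %d bins %.0f-%.0f Hz (pad %.2g s, taper %s)\n",
    x$subject, x$session, length(x$frequencies_hz),
    min(x$frequencies_hz), max(x$frequencies_hz), x$pad_seconds, x$taper$kind
  ))
  invisible(x)
}

#' Average power spectra element-wise
#'
#' Arithmetic mean over a collection of spectra sharing one frequency grid.
#' The analysis convention is to average sessions within subject first
#' (`over = "sessions"`, requiring a single subject) and only then across
#' subjects (`over = "subjects"`).
#'
#' @param spectra list of `power_spectrum` objects with identical grids.
#' @param over `"sessions"` or `"subjects"`, documenting (and checking) the
#'   averaging level.
#' @return A `power_spectrum`; `session` (or both identifiers) set to `NA`.
#' @export
average_spectra <- function(spectra, over = c("sessions", "subjects")) {
  over <- match.arg(over)
  stopifnot(is.list(spectra), length(spectra) >= 1)
  for (sp in spectra) stopifnot(inherits(sp, "power_spectrum"))
  grid <- spectra[[1]]$frequencies_hz
  for (sp in spectra) {
    if (length(sp$frequencies_hz) != length(grid) ||
        max(abs(sp$frequencies_hz - grid)) > 1e-9) {
      stop_invalid("frequency grids differ across spectra")
    }
  }
  subjects <- unique(vapply(spectra, function(sp) as.character(sp$subject),
                            character(1)))
  if (over == "sessions" && length(subjects) > 1) {
    stop_invalid("averaging over sessions requires a single subject")
  }
  pw <- rowMeans(vapply(spectra, function(sp) sp$power, numeric(length(grid))))
  new_power_spectrum(
    subject = if (over == "sessions") spectra[[1]]$subject else NA,
    session = NA,
    frequencies_hz = grid, power = pw,
    pad_seconds = spectra[[1]]$pad_seconds, taper = spectra[[1]]$taper
  )
}

#' Stack spectra into a matrix
#'
#' @param spectra list of `power_spectrum` or `surrogate_spectrum` objects on
#'   one grid.
#' @return Numeric matrix, one row per spectrum, columns named by frequency;
#'   row names from subjects.
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  grid <- spectra[[1]]$frequencies_hz
  m <- t(vapply(spectra, function(sp) {
    if (length(sp$frequencies_hz) != length(grid) ||
        max(abs(sp$frequencies_hz - grid)) > 1e-9) {
      stop_invalid("frequency grids differ across spectra")
    }
    sp$power
  }, numeric(length(grid))))
  rownames(m) <- vapply(spectra, function(sp) as.character(sp$subject),
                        character(1))
  colnames(m) <- format(grid, trim = TRUE)
  attr(m, "frequencies_hz") <- grid
  m
}

#' Lowest frequency completing a full cycle in a window
#'
#' A window of `window_seconds` accommodates one full cycle only for
#' frequencies at or above `1 / window_seconds`; spectral estimates below
#' that bound rest on partial cycles and deserve caution. For the 288 ms
#' span between the shortest and longest printed delays this is 3.47 Hz.
#'
#' @param window_seconds window duration in seconds.
#' @return Frequency in Hz.
#' @export
min_full_cycle_frequency <- function(window_seconds) {
  stopifnot(is.numeric(window_seconds), all(window_seconds > 0))
  1 / window_seconds
}
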