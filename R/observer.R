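#' Logistic observer model
#'
#' A synthetic observer with two psychometric functions: a detection function
#' for the subliminal ring (probability of reporting "seen" increases with
#' Weber contrast) and a temporal-integration function for the two-image task
#' (probability of locating the empty grid position decreases with the
#' stimulus onset asynchrony, SOA, between the images). The integration
#' function passes through exactly 50% accuracy at `soa_threshold_ms`, the
#' quantity the adaptive SOA staircase targets.
#'
#' Detection: `P(seen | c) = (1 - lapse_rate) * plogis(contrast_slope * (c - contrast_threshold))`,
#' so at threshold contrast with no lapses the observer reports "seen" half
#' the time, and an arbitrarily steep observer far above threshold says
#' "seen" with probability `1 - lapse_rate`.
#'
#' Integration accuracy: a decreasing logistic between `1 - lapse_rate` and
#' `guess_rate` (chance for a 16-alternative location report is 1/16),
#' horizontally anchored so that accuracy equals 0.5 at `soa_threshold_ms`.
#'
#' @param contrast_threshold Weber-contrast fraction at which detection
#'   probability is 50% (lapse-free); dimensionless.
#' @param contrast_slope logistic steepness per contrast unit, `>= 0`.
#' @param soa_threshold_ms SOA in ms at which integration accuracy is 50%.
#' @param soa_slope logistic steepness per ms, `>= 0`.
#' @param lapse_rate lapse probability in `[0, 0.1]`.
#' @param guess_rate chance accuracy for the location report, in `[0, 1)`.
#' @return An object of class `observer_model`.
#' @examples
#' obs <- observer_model()
#' soa_accuracy(obs, obs$soa_threshold_ms) # exactly 0.5
#' @export
observer_model <- function(contrast_threshold = 0.05,
                           contrast_slope = 80,
                           soa_threshold_ms = 42,
                           soa_slope = 0.12,
                           lapse_rate = 0.02,
                           guess_rate = 1 / 16) {
  stopifnot(
    is_scalar_number(contrast_threshold),
    is_scalar_number(contrast_slope), contrast_slope >= 0,
    is_scalar_number(soa_threshold_ms), soa_threshold_ms >= 0,
    is_scalar_number(soa_slope), soa_slope >= 0,
    is_scalar_number(lapse_rate), lapse_rate >= 0, lapse_rate <= 0.1,
    is_scalar_number(guess_rate), guess_rate >= 0, guess_rate < 1
  )
  if (1 - lapse_rate <= 0.5 || guess_rate >= 0.5) {
    stop_invalid(
      "integration accuracy cannot pass through 50%: need guess_rate < 0.5 ",
      "and 1 - lapse_rate > 0.5"
    )
  }
  structure(
    list(
      contrast_threshold = contrast_threshold,
      contrast_slope = contrast_slope,
      soa_threshold_ms = soa_threshold_ms,
      soa_slope = soa_slope,
      lapse_rate = lapse_rate,
      guess_rate = guess_rate
    ),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model>\n")
  cat(sprintf(
    "  detection : threshold %.3f (Weber), slope %.1f, lapse %.3f\n",
    x$contrast_threshold, x$contrast_slope, x$lapse_rate
  ))
  cat(sprintf(
    "  integration: 50%% accuracy at SOA %.1f ms, slope %.3f /ms, guess %.3f\n",
    x$soa_threshold_ms, x$soa_slope, x$guess_rate
  ))
  invisible(x)
}

#' Detection probability of the subliminal stimulus
#'
#' @param observer an [observer_model()].
#' @param contrast Weber-contrast fraction(s), `>= 0`.
#' @return Probability of a "seen" report, vectorised over `contrast`.
#' @export
detection_probability <- function(observer, contrast) {
  stopifnot(inherits(observer, "observer_model"), is.numeric(contrast))
  if (any(contrast < 0)) stop_invalid("contrast must be nonnegative")
  (1 - observer$lapse_rate) *
    stats::plogis(observer$contrast_slope * (contrast - observer$contrast_threshold))
}

#' Simulate yes/no detection reports
#'
#' Draws Bernoulli "seen" responses from the observer's detection
#' psychometric function.
#'
#' @inheritParams detection_probability
#' @param n number of independent reports to draw.
#' @return Logical vector of length `n` (`TRUE` = "seen").
#' @export
simulate_detection <- function(observer, contrast, n = 1L) {
  p <- detection_probability(observer, contrast)
  stats::runif(n) < p
}

#' Integration accuracy as a function of SOA
#'
#' Decreasing logistic between `1 - lapse_rate` (easy, short SOA) and
#' `guess_rate` (impossible, long SOA), anchored so accuracy is exactly 0.5
#' at the observer's `soa_threshold_ms`.
#'
#' @inheritParams detection_probability
#' @param soa_ms stimulus onset asynchrony in ms, `>= 0`, vectorised.
#' @return Probability of a correct location report.
#' @export
soa_accuracy <- function(observer, soa_ms) {
  stopifnot(inherits(observer, "observer_model"), is.numeric(soa_ms))
  if (any(soa_ms < 0)) stop_invalid("soa_ms must be nonnegative")
  lo <- observer$guess_rate
  hi <- 1 - observer$lapse_rate
  if (observer$soa_slope == 0) {
    return(rep(0.5, length(soa_ms)))
  }
  # anchor so that accuracy(soa_threshold_ms) == 0.5
  mid <- observer$soa_threshold_ms +
    stats::qlogis((0.5 - lo) / (hi - lo)) / observer$soa_slope
  lo + (hi - lo) * stats::plogis(-observer$soa_slope * (soa_ms - mid))
}
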