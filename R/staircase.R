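#' Adaptive contrast staircase for the subliminal stimulus
#'
#' Calibrates the grey value of the subliminal ring so that it is just not
#' consciously perceived. On each evaluated trial the stimulus is shown at
#' the current grey value and the observer reports "seen"/"not seen":
#'
#' * "yes" decreases the grey value by `step` (floored at `background_grey`)
#'   and resets the "no" streak;
#' * 10 consecutive evaluated "no" responses increase the grey value by
#'   `step` once; the streak counter keeps running;
#' * 20 consecutive evaluated "no" responses terminate the staircase, and the
#'   momentary grey value is the calibrated subliminal level.
#'
#' The streak counter is deliberately not reset by the increment at 10 —
#' under the alternative reading (reset at 10) a 20-"no" streak could never
#' complete without first triggering another increment, so the termination
#' rule would be unreachable.
#'
#' Sham trials at random grey values are interleaved with probability
#' `sham_prob`; they are logged (`evaluated = FALSE`) but never change the
#' staircase state, mirroring the non-evaluated filler stimuli used to keep
#' observers from tracking the staircase.
#'
#' @param observer an [observer_model()]; its detection function is queried
#'   at the Weber contrast of the shown grey value against
#'   `background_grey`.
#' @param start_grey initial grey value (default 0.47).
#' @param background_grey background grey value and lower floor for the
#'   staircase (default 0.38, i.e. zero contrast).
#' @param step grey-value step (default 0.01, a 2.6% simple-Weber-contrast
#'   step on the 0.38 background).
#' @param max_trials maximum number of trials (evaluated + sham) before
#'   giving up; the result then has `terminated = FALSE`.
#' @param sham_prob probability that any given trial is a non-evaluated sham
#'   at a random grey value in `sham_range`.
#' @param sham_range range of sham grey values.
#' @param seed optional integer seed for reproducibility.
#' @return A `staircase_result`: list with `kind = "contrast"`, a
#'   `trial_log` data frame (`trial`, `level`, `response`, `evaluated`),
#'   `terminal_level`, `terminated`, `n_trials` and `n_evaluated`.
#' @examples
#' blind <- observer_model(contrast_threshold = 10) # never says "yes"
#' r <- run_contrast_staircase(blind, sham_prob = 0, seed = 1)
#' r$terminal_level # 0.48: one increment at the 10th consecutive "no"
#' @export
run_contrast_staircase <- function(observer,
                                   start_grey = 0.47,
                                   background_grey = 0.38,
                                   step = 0.01,
                                   max_trials = 1000L,
                                   sham_prob = 0.2,
                                   sham_range = c(0.38, 0.57),
                                   seed = NULL) {
  stopifnot(
    inherits(observer, "observer_model"),
    is_scalar_number(start_grey), is_scalar_number(background_grey),
    start_grey >= background_grey,
    is_scalar_number(step), step > 0,
    is_scalar_number(max_trials), max_trials >= 1,
    is_scalar_number(sham_prob), sham_prob >= 0, sham_prob < 1
  )
  with_seed(seed, {
    level <- start_grey
    no_streak <- 0L
    lev <- resp <- numeric(max_trials)
    evalf <- logical(max_trials)
    terminated <- FALSE
    n <- 0L
    n_eval <- 0L
    while (n < max_trials) {
      n <- n + 1L
      if (stats::runif(1) < sham_prob) {
        g <- stats::runif(1, sham_range[1], sham_range[2])
        lev[n] <- g
        resp[n] <- as.numeric(simulate_detection(observer, weber_contrast(g, background_grey)))
        evalf[n] <- FALSE
        next
      }
      n_eval <- n_eval + 1L
      seen <- simulate_detection(observer, weber_contrast(level, background_grey))
      lev[n] <- level
      resp[n] <- as.numeric(seen)
      evalf[n] <- TRUE
      if (seen) {
        level <- max(level - step, background_grey)
        no_streak <- 0L
      } else {
        no_streak <- no_streak + 1L
        if (no_streak == 10L) level <- level + step
        if (no_streak == 20L) {
          terminated <- TRUE
          break
        }
      }
    }
    new_staircase_result(
      kind = "contrast",
      trial_log = data.frame(
        trial = seq_len(n), level = lev[seq_len(n)],
        response = as.logical(resp[seq_len(n)]), evaluated = evalf[seq_len(n)]
      ),
      terminal_level = level,
      terminated = terminated,
      n_trials = n,
      n_evaluated = n_eval
    )
  })
}

#' Adaptive SOA staircase for the integration task
#'
#' Calibrates the threshold stimulus onset asynchrony (SOA) at which the
#' two-image integration task is solved with ~50% accuracy. A 2-up/2-down
#' rule is used: two consecutive correct reports increase the SOA by
#' `step_ms` (making the task harder), two consecutive incorrect reports
#' decrease it (floored at 0 ms); either update resets both streaks. The
#' staircase terminates once the SOAs of the last 20 evaluated trials are
#' stable, i.e. their variance is below `stability_variance` (ms^2). Because
#' one step is a full video frame (16.7 ms), this effectively requires 20
#' consecutive evaluated trials at an unchanged SOA, so stochastic observers
#' rarely terminate; the 2-up/2-down rule nevertheless concentrates the
#' visited levels around the 50% point.
#'
#' Non-evaluated sham trials at random SOAs (0 to 8 frames) are interleaved
#' with probability `sham_prob` and logged with `evaluated = FALSE`.
#'
#' @inheritParams run_contrast_staircase
#' @param start_soa_ms starting SOA (default 26 ms).
#' @param step_ms SOA step, default one video frame ([frame_duration_ms()]).
#' @param stability_window number of trailing evaluated trials over which
#'   stability is assessed (default 20).
#' @param stability_variance variance threshold in ms^2 (default 0.5).
#' @return A `staircase_result` with `kind = "soa"`.
#' @export
run_soa_staircase <- function(observer,
                              start_soa_ms = 26,
                              step_ms = frame_duration_ms(),
                              max_trials = 1000L,
                              sham_prob = 0.2,
                              stability_window = 20L,
                              stability_variance = 0.5,
                              seed = NULL) {
  stopifnot(
    inherits(observer, "observer_model"),
    is_scalar_number(start_soa_ms), start_soa_ms >= 0,
    is_scalar_number(step_ms), step_ms > 0,
    is_scalar_number(max_trials), max_trials >= 1,
    is_scalar_number(sham_prob), sham_prob >= 0, sham_prob < 1,
    is_scalar_number(stability_window), stability_window >= 2,
    is_scalar_number(stability_variance), stability_variance > 0
  )
  with_seed(seed, {
    soa <- start_soa_ms
    cc <- ii <- 0L
    lev <- resp <- numeric(max_trials)
    evalf <- logical(max_trials)
    eval_levels <- numeric(max_trials)
    terminated <- FALSE
    n <- 0L
    n_eval <- 0L
    while (n < max_trials) {
      n <- n + 1L
      if (stats::runif(1) < sham_prob) {
        s <- sample(0:8, 1L) * step_ms
        lev[n] <- s
        resp[n] <- as.numeric(stats::runif(1) < soa_accuracy(observer, s))
        evalf[n] <- FALSE
        next
      }
      n_eval <- n_eval + 1L
      correct <- stats::runif(1) < soa_accuracy(observer, soa)
      lev[n] <- soa
      eval_levels[n_eval] <- soa
      resp[n] <- as.numeric(correct)
      evalf[n] <- TRUE
      if (correct) {
        cc <- cc + 1L
        ii <- 0L
        if (cc == 2L) {
          soa <- soa + step_ms
          cc <- 0L
        }
      } else {
        ii <- ii + 1L
        cc <- 0L
        if (ii == 2L) {
          soa <- max(soa - step_ms, 0)
          ii <- 0L
        }
      }
      if (n_eval >= stability_window) {
        recent <- eval_levels[(n_eval - stability_window + 1L):n_eval]
        if (stats::var(recent) < stability_variance) {
          terminated <- TRUE
          break
        }
      }
    }
    new_staircase_result(
      kind = "soa",
      trial_log = data.frame(
        trial = seq_len(n), level = lev[seq_len(n)],
        response = as.logical(resp[seq_len(n)]), evaluated = evalf[seq_len(n)]
      ),
      terminal_level = soa,
      terminated = terminated,
      n_trials = n,
      n_evaluated = n_eval
    )
  })
}

new_staircase_result <- function(kind, trial_log, terminal_level, terminated,
                                 n_trials, n_evaluated) {
  structure(
    list(
      kind = kind, trial_log = trial_log, terminal_level = terminal_level,
      terminated = terminated, n_trials = n_trials, n_evaluated = n_evaluated
    ),
    class = "staircase_result"
  )
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "<staircase_result: %s> %d trials (%d evaluated), %s, terminal level %.3f\n",
    x$kind, x$n_trials, x$n_evaluated,
    if (x$terminated) "terminated" else "NOT terminated", x$terminal_level
  ))
  invisible(x)
}
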