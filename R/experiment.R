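#' Oscillatory accuracy component
#'
#' One additive cosine modulation of threshold-SOA accuracy as a function of
#' the delay between subliminal stimulus and first target image:
#' `amplitude * cos(2*pi*frequency_hz*t + phase_rad)` with `t` the delay in
#' seconds.
#'
#' @param frequency_hz modulation frequency in Hz, in `(0, 30)` (below the
#'   30 Hz Nyquist limit of the one-frame sampling grid).
#' @param amplitude modulation depth (accuracy units), `|amplitude| <= 0.5`.
#' @param phase_rad phase in radians.
#' @return An object of class `osc_component`.
#' @export
osc_component <- function(frequency_hz, amplitude, phase_rad = 0) {
  stopifnot(
    is_scalar_number(frequency_hz), frequency_hz > 0, frequency_hz < 30,
    is_scalar_number(amplitude), abs(amplitude) <= 0.5,
    is_scalar_number(phase_rad)
  )
  structure(
    list(frequency_hz = frequency_hz, amplitude = amplitude, phase_rad = phase_rad),
    class = "osc_component"
  )
}

#' Default delay grid: 19 video frames from ~317 to ~617 ms before target
#'
#' Delays are specified in whole video frames (exact frame duration 1/60 s)
#' and reported as positive milliseconds before the first target image. The
#' default spans frames 19 to 37, i.e. 19 evenly spaced delays roughly
#' 312-617 ms before the target. Nineteen delays times 20 threshold-SOA
#' trials gives the canonical 380 threshold trials per session; an 18-point
#' grid ending exactly at 600 ms would not reproduce that trial count.
#'
#' @param first_frame first delay in frames (default 19).
#' @param n_delays number of delays (default 19).
#' @return Numeric vector of delays in ms, strictly increasing, spaced by one
#'   frame.
#' @export
default_delay_grid <- function(first_frame = 19L, n_delays = 19L) {
  stopifnot(first_frame >= 1, n_delays >= 2)
  (first_frame + seq_len(n_delays) - 1) * frame_duration_ms()
}

#' Configuration for a synthetic dense-sampling experiment
#'
#' Bundles the design of one synthetic experiment: subjects, sessions, the
#' subliminal-target delay grid, threshold-SOA trials per delay, the
#' accuracy model for threshold trials (base level, polynomial trends in
#' delay, additive cosine components), the catch-trial rate, and a master
#' seed.
#'
#' For a threshold-SOA trial at delay `t` (ms), the success probability is
#' `clamp(base_accuracy + trend_linear*t + trend_quadratic*t^2 +
#' sum_i a_i*cos(2*pi*f_i*t/1000 + phi_i), 0, 1)`. Clamping events are
#' counted and reported as the `n_clamped` attribute of the generated trial
#' table.
#'
#' @param n_subjects,n_sessions design size (defaults 19 and 2).
#' @param delay_grid_ms strictly increasing, evenly spaced delays in ms
#'   (default [default_delay_grid()]).
#' @param trials_per_delay threshold-SOA trials per delay per session
#'   (default 20).
#' @param base_accuracy baseline accuracy at threshold SOA (default 0.5).
#' @param trend_linear,trend_quadratic accuracy drift per ms and per ms^2.
#' @param components list of [osc_component()]s (default none).
#' @param catch_rate probability that any trial slot is a catch trial, in
#'   `[0, 1)` (default 0.1; real and fake catch trials are equiprobable).
#' @param false_alarm_rate probability of a "seen" report on a fake catch
#'   trial (default 0.1); real catch trials use the observer's detection
#'   function with the same false-alarm floor.
#' @param control_trials_per_delay trials per delay per session for each of
#'   the four control SOA conditions (default 2).
#' @param stimulus_contrast Weber contrast of the subliminal ring used on
#'   real catch trials; `NULL` (default) places it one grey step (0.01 on a
#'   0.38 background) below the observer's detection threshold, emulating a
#'   successfully calibrated staircase.
#' @param seed integer master seed; `NULL` uses the current RNG state.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 19L,
                              n_sessions = 2L,
                              delay_grid_ms = default_delay_grid(),
                              trials_per_delay = 20L,
                              base_accuracy = 0.5,
                              trend_linear = 0,
                              trend_quadratic = 0,
                              components = list(),
                              catch_rate = 0.1,
                              false_alarm_rate = 0.1,
                              control_trials_per_delay = 2L,
                              stimulus_contrast = NULL,
                              seed = NULL) {
  stopifnot(
    is_scalar_number(n_subjects), n_subjects >= 1,
    is_scalar_number(n_sessions), n_sessions >= 1,
    is.numeric(delay_grid_ms), length(delay_grid_ms) >= 2,
    is_scalar_number(trials_per_delay), trials_per_delay >= 1,
    is_scalar_number(base_accuracy), base_accuracy >= 0, base_accuracy <= 1,
    is_scalar_number(trend_linear), is_scalar_number(trend_quadratic),
    is.list(components),
    is_scalar_number(catch_rate), catch_rate >= 0, catch_rate < 1,
    is_scalar_number(false_alarm_rate),
    false_alarm_rate >= 0, false_alarm_rate <= 1,
    is_scalar_number(control_trials_per_delay), control_trials_per_delay >= 0
  )
  d <- diff(delay_grid_ms)
  if (any(d <= 0)) stop_invalid("delay_grid_ms must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
    stop_invalid("delay_grid_ms must be evenly spaced")
  }
  for (cmp in components) {
    if (!inherits(cmp, "osc_component")) {
      stop_invalid("components must be a list of osc_component objects")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_sessions = as.integer(n_sessions),
      delay_grid_ms = delay_grid_ms,
      trials_per_delay = as.integer(trials_per_delay),
      base_accuracy = base_accuracy,
      trend_linear = trend_linear,
      trend_quadratic = trend_quadratic,
      components = components,
      catch_rate = catch_rate,
      false_alarm_rate = false_alarm_rate,
      control_trials_per_delay = as.integer(control_trials_per_delay),
      stimulus_contrast = stimulus_contrast,
      seed = seed
    ),
    class = "experiment_config"
  )
}

# Success probability of a threshold-SOA trial at each delay, with clamp
# bookkeeping. Returns list(p, n_clamped).
modulated_accuracy <- function(config, delays_ms = config$delay_grid_ms) {
  t_ms <- delays_ms
  p <- config$base_accuracy +
    config$trend_linear * t_ms +
    config$trend_quadratic * t_ms^2
  for (cmp in config$components) {
    p <- p + cmp$amplitude *
      cos(2 * pi * cmp$frequency_hz * t_ms / 1000 + cmp$phase_rad)
  }
  clamped <- p < 0 | p > 1
  list(p = pmin(pmax(p, 0), 1), n_clamped = sum(clamped))
}

soa_conditions <- function() {
  c("short", "intermediate_minus", "threshold", "intermediate_plus", "long")
}

# SOA in ms for each named condition given a session's threshold SOA.
condition_soas <- function(threshold_soa_ms) {
  f <- frame_duration_ms()
  c(
    short = 0,
    intermediate_minus = max(threshold_soa_ms - f, 0),
    threshold = threshold_soa_ms,
    intermediate_plus = threshold_soa_ms + f,
    long = threshold_soa_ms + 48
  )
}

#' Generate a full synthetic trial-level dataset
#'
#' Emits one trial table for the whole design in `config`. Threshold-SOA
#' trials are Bernoulli draws from the delay-dependent accuracy model (base
#' level, trends and cosine components, clamped to `[0, 1]`); the four
#' control SOA conditions (short 0 ms, threshold +/- one frame, threshold
#' + 48 ms) draw from the observer's SOA psychometric function; real catch
#' trials draw a "seen" report from the observer's detection function (with
#' the false-alarm floor) and fake catch trials from the false-alarm rate
#' alone. Each trial slot is independently a catch trial with probability
#' `catch_rate`, split evenly between real and fake. Trials are shuffled
#' within session and indexed in presentation order.
#'
#' The result is deterministic given `config$seed`: identical seeds yield
#' byte-identical trial tables.
#'
#' @param config an [experiment_config()].
#' @param observers a single [observer_model()] recycled for all subjects, or
#'   a list with one observer per subject; `NULL` uses the default observer
#'   for everyone.
#' @return A data frame with columns `subject`, `session`, `trial_index`,
#'   `delay_ms`, `soa_condition`, `soa_ms`, `correct`, `reported_seen`
#'   (exactly one of `correct`/`reported_seen` is non-`NA` per trial, by
#'   trial kind), with attribute `n_clamped` counting accuracy-model clamping
#'   events.
#' @examples
#' cfg <- experiment_config(n_subjects = 2, n_sessions = 1, seed = 1)
#' trials <- generate_experiment(cfg)
#' table(trials$soa_condition)
#' @export
generate_experiment <- function(config, observers = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$delay_grid_ms) == 0) stop_invalid("empty delay grid")
  if (is.null(observers)) observers <- observer_model()
  if (inherits(observers, "observer_model")) {
    observers <- rep(list(observers), config$n_subjects)
  }
  if (length(observers) != config$n_subjects) {
    stop_invalid("need one observer per subject (or a single one to recycle)")
  }
  with_seed(config$seed, {
    acc <- modulated_accuracy(config)
    pieces <- vector("list", config$n_subjects * config$n_sessions)
    k <- 0L
    n_clamped <- 0L
    for (s in seq_len(config$n_subjects)) {
      obs <- observers[[s]]
      stim_contrast <- config$stimulus_contrast %||%
        max(obs$contrast_threshold - weber_contrast(0.39, 0.38), 0)
      p_seen_real <- detection_probability(obs, stim_contrast)
      p_seen_real <- p_seen_real + (1 - p_seen_real) * config$false_alarm_rate
      for (ses in seq_len(config$n_sessions)) {
        k <- k + 1L
        pieces[[k]] <- generate_session(
          config, obs, acc$p,
          subject = sprintf("S%02d", s), session = ses,
          p_seen_real = p_seen_real
        )
        n_clamped <- n_clamped + acc$n_clamped
      }
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    attr(out, "n_clamped") <- n_clamped
    out
  })
}

# One subject-session block; RNG state flows from the caller.
generate_session <- function(config, obs, p_threshold, subject, session,
                             p_seen_real) {
  grid <- config$delay_grid_ms
  nd <- length(grid)

  # threshold-SOA trials
  thr_delay <- rep(grid, each = config$trials_per_delay)
  thr_p <- rep(p_threshold, each = config$trials_per_delay)
  thr_correct <- stats::runif(length(thr_delay)) < thr_p

  # control-SOA trials
  soas <- condition_soas(obs$soa_threshold_ms)
  ctl_cond <- ctl_delay <- ctl_soa <- ctl_correct <- NULL
  if (config$control_trials_per_delay > 0) {
    conds <- setdiff(names(soas), "threshold")
    ctl_cond <- rep(conds, each = nd * config$control_trials_per_delay)
    ctl_delay <- rep(rep(grid, each = config$control_trials_per_delay),
                     times = length(conds))
    ctl_soa <- soas[ctl_cond]
    ctl_correct <- stats::runif(length(ctl_cond)) <
      soa_accuracy(obs, ctl_soa)
  }

  n_task <- length(thr_delay) + length(ctl_cond)
  # each trial slot is a catch with probability catch_rate, so the number of
  # catches interleaved among n_task task trials is negative binomial
  n_catch <- if (config$catch_rate > 0) {
    stats::rnbinom(1, size = n_task, prob = 1 - config$catch_rate)
  } else 0L
  catch_real <- if (n_catch > 0) stats::runif(n_catch) < 0.5 else logical(0)
  catch_seen <- if (n_catch > 0) {
    stats::runif(n_catch) <
      ifelse(catch_real, p_seen_real, config$false_alarm_rate)
  } else logical(0)

  df <- data.frame(
    subject = subject,
    session = as.integer(session),
    trial_index = NA_integer_,
    delay_ms = c(thr_delay, ctl_delay, rep(NA_real_, n_catch)),
    soa_condition = c(
      rep("threshold", length(thr_delay)),
      ctl_cond,
      ifelse(catch_real, "catch_real", "catch_fake")
    ),
    soa_ms = c(
      rep(soas[["threshold"]], length(thr_delay)),
      unname(ctl_soa),
      rep(NA_real_, n_catch)
    ),
    correct = c(thr_correct, ctl_correct, rep(NA, n_catch)),
    reported_seen = c(rep(NA, n_task), catch_seen),
    stringsAsFactors = FALSE
  )
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  df$trial_index <- seq_len(nrow(df))
  df
}
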