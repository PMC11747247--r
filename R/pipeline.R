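trial_columns <- c(
  "subject", "session", "trial_index", "delay_ms",
  "soa_condition", "soa_ms", "correct", "reported_seen"
)

valid_conditions <- function() c(soa_conditions(), "catch_real", "catch_fake")

#' Write a trial table to CSV
#'
#' Columns `subject,session,trial_index,delay_ms,soa_condition,soa_ms,correct,reported_seen`;
#' non-applicable fields (e.g. `delay_ms` on catch trials) are left empty.
#'
#' @param trials trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials), all(trial_columns %in% names(trials)))
  utils::write.csv(trials[trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Expects the exact header written by [write_trials()]. Malformed rows
#' (unknown condition labels, non-numeric delays or SOAs, correctness flags
#' other than TRUE/FALSE, trials populating both or neither of
#' `correct`/`reported_seen`) are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated trial table (empty data frame for a header-only file).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  if (!identical(names(raw), trial_columns)) {
    stop_invalid(
      "schema error: expected header ",
      paste(trial_columns, collapse = ","), " but found ",
      paste(names(raw), collapse = ",")
    )
  }
  n <- nrow(raw)
  if (n == 0) {
    out <- data.frame(
      subject = character(0), session = integer(0),
      trial_index = integer(0), delay_ms = numeric(0),
      soa_condition = character(0), soa_ms = numeric(0),
      correct = logical(0), reported_seen = logical(0),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  lines <- seq_len(n) + 1L # header is line 1
  problems <- character(0)
  num_or_na <- function(x, field) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(v))
    if (length(bad)) {
      problems <<- c(problems, sprintf(
        "line %d: non-numeric %s '%s'", lines[bad], field, x[bad]
      ))
    }
    v[!nzchar(x)] <- NA_real_
    v
  }
  lgl_or_na <- function(x, field) {
    up <- toupper(trimws(x))
    v <- rep(NA, length(x))
    v[up %in% c("TRUE", "1")] <- TRUE
    v[up %in% c("FALSE", "0")] <- FALSE
    bad <- which(nzchar(x) & !up %in% c("TRUE", "FALSE", "1", "0", "NA"))
    if (length(bad)) {
      problems <<- c(problems, sprintf(
        "line %d: invalid %s '%s' (expected TRUE/FALSE)",
        lines[bad], field, x[bad]
      ))
    }
    v
  }
  delay <- num_or_na(raw$delay_ms, "delay_ms")
  soa <- num_or_na(raw$soa_ms, "soa_ms")
  tidx <- num_or_na(raw$trial_index, "trial_index")
  sess <- num_or_na(raw$session, "session")
  correct <- lgl_or_na(raw$correct, "correct")
  seen <- lgl_or_na(raw$reported_seen, "reported_seen")
  bad_cond <- which(!raw$soa_condition %in% valid_conditions())
  if (length(bad_cond)) {
    problems <- c(problems, sprintf(
      "line %d: unknown soa_condition '%s'",
      lines[bad_cond], raw$soa_condition[bad_cond]
    ))
  }
  both <- which(!is.na(correct) & !is.na(seen))
  neither <- which(is.na(correct) & is.na(seen))
  if (length(both)) {
    problems <- c(problems, sprintf(
      "line %d: both correct and reported_seen populated", lines[both]
    ))
  }
  if (length(neither)) {
    problems <- c(problems, sprintf(
      "line %d: neither correct nor reported_seen populated", lines[neither]
    ))
  }
  if (length(problems)) {
    stop_invalid(
      "malformed trial table (", length(problems), " problem(s)):\n  ",
      paste(utils::head(problems, 20), collapse = "\n  ")
    )
  }
  data.frame(
    subject = raw$subject, session = as.integer(sess),
    trial_index = as.integer(tidx), delay_ms = delay,
    soa_condition = raw$soa_condition, soa_ms = soa,
    correct = correct, reported_seen = seen,
    stringsAsFactors = FALSE
  )
}

#' Configuration of a full analysis run
#'
#' Bundles the data source and all stage settings of [run_pipeline()].
#' Either `trials` (a trial table or a CSV path) is analysed, or a synthetic
#' experiment is generated from `experiment` (an [experiment_config()]) and
#' `observers`.
#'
#' @param trials trial table, CSV path, or `NULL` to generate synthetically.
#' @param experiment an [experiment_config()] used when `trials` is `NULL`.
#' @param observers passed to [generate_experiment()].
#' @param detrend_order polynomial detrend order, 1 (default) or 2.
#' @param pad_seconds,taper,fmin_hz,fmax_hz spectral settings (see
#'   [compute_power_spectrum()]).
#' @param methods surrogate methods to run: any of `"time_shuffle"`,
#'   `"random_accuracy"`, `"ar_model"`.
#' @param n_surrogate_reps surrogate repetitions per session (default 1000).
#' @param surrogate_reduce `"median"` (convention) or `"mean"` (see
#'   [reduce_surrogates()]).
#' @param n_permutations label permutations for the cluster test (default
#'   10000).
#' @param alpha cluster-forming tail probability (default 0.05).
#' @param tail `"two_sided"` or `"one_sided_positive"`.
#' @param seed master seed; every stage derives its own stream from it via
#'   [derive_seed()].
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @param verbose emit per-stage progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trials = NULL,
                       experiment = experiment_config(),
                       observers = NULL,
                       detrend_order = 1L,
                       pad_seconds = 1,
                       taper = taper_spec(),
                       fmin_hz = 1, fmax_hz = 29,
                       methods = c("time_shuffle", "random_accuracy",
                                   "ar_model"),
                       n_surrogate_reps = 1000L,
                       surrogate_reduce = "median",
                       n_permutations = 10000L,
                       alpha = 0.05,
                       tail = "two_sided",
                       seed = 1L,
                       out_dir = NULL,
                       verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  surrogate_reduce <- match.arg(surrogate_reduce, c("median", "mean"))
  tail <- match.arg(tail, c("two_sided", "one_sided_positive"))
  stopifnot(
    detrend_order %in% 1:2,
    is_scalar_number(n_surrogate_reps), n_surrogate_reps >= 1,
    is_scalar_number(n_permutations), n_permutations >= 1,
    is_scalar_number(alpha), alpha > 0, alpha < 1,
    is_scalar_number(seed)
  )
  if (is.character(trials) && !file.exists(trials)) {
    stop_invalid("trials file not found: ", trials)
  }
  structure(
    list(
      trials = trials, experiment = experiment, observers = observers,
      detrend_order = as.integer(detrend_order),
      pad_seconds = pad_seconds, taper = taper,
      fmin_hz = fmin_hz, fmax_hz = fmax_hz,
      methods = methods,
      n_surrogate_reps = as.integer(n_surrogate_reps),
      surrogate_reduce = surrogate_reduce,
      n_permutations = as.integer(n_permutations),
      alpha = alpha, tail = tail,
      seed = as.integer(seed), out_dir = out_dir, verbose = verbose
    ),
    class = "run_config"
  )
}

#' Run the full behavioural-oscillation analysis
#'
#' Executes, for each subject and session: accuracy aggregation by delay,
#' polynomial detrending, the zero-padded single-taper power spectrum; then,
#' per surrogate method, the surrogate ensemble with identical spectral
#' settings, its median-over-repetitions / mean-over-sessions reduction, and
#' the cluster-based permutation test of observed versus surrogate power
#' across subjects. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @return An object of class `pipeline_result`: `trials`, `series` (raw
#'   [delay_series()] per subject/session), `observed` (per-subject
#'   spectra matrix), `group_spectrum`, `surrogates` (per-subject
#'   matrices by method), `tests` (named list of `cluster_test`), and
#'   `manifest` (settings, seed, config hash, row counts per stage).
#' @examples
#' cfg <- run_config(
#'   experiment = experiment_config(n_subjects = 4, n_sessions = 1),
#'   methods = "random_accuracy", n_surrogate_reps = 20,
#'   n_permutations = 100, seed = 7
#' )
#' res <- run_pipeline(cfg)
#' res$tests$random_accuracy
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (isTRUE(config$verbose)) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("pipeline stage '", name, "' failed: ",
                   conditionMessage(e))
    })
  }

  # --- data ---------------------------------------------------------------
  trials <- stage("input", {
    if (is.null(config$trials)) {
      ex <- config$experiment
      ex$seed <- derive_seed(config$seed, "generate")
      generate_experiment(ex, config$observers)
    } else if (is.character(config$trials)) {
      read_trials(config$trials)
    } else {
      config$trials
    }
  })
  say("input: %d trials", nrow(trials))

  subjects <- sort(unique(trials$subject))
  sessions <- sort(unique(trials$session))

  # --- aggregate + detrend + observed spectra -----------------------------
  series <- list()
  spectra <- list()
  for (s in subjects) {
    for (k in sessions) {
      key <- paste(s, k, sep = "/")
      raw <- stage("aggregate", aggregate_accuracy(trials, s, k))
      series[[key]] <- raw
      det <- stage("detrend", detrend_series(raw, config$detrend_order))
      spectra[[key]] <- stage("spectrum", compute_power_spectrum(
        det, config$pad_seconds, config$taper, config$fmin_hz, config$fmax_hz
      ))
    }
  }
  say("aggregate: %d subject-session series of %d delays",
      length(series), length(series[[1]]$delays_ms))

  subj_spectra <- lapply(subjects, function(s) {
    average_spectra(spectra[paste(s, sessions, sep = "/")], over = "sessions")
  })
  observed <- spectra_matrix(subj_spectra)
  group_spectrum <- average_spectra(subj_spectra, over = "subjects")
  say("spectra: %d subjects x %d frequency bins", nrow(observed),
      ncol(observed))

  # --- surrogates + cluster tests ----------------------------------------
  surrogates <- list()
  tests <- list()
  for (method in config$methods) {
    sur_subj <- lapply(subjects, function(s) {
      reps <- lapply(sessions, function(k) {
        key <- paste(s, k, sep = "/")
        sseed <- derive_seed(config$seed, paste(method, key))
        raw <- series[[key]]
        switch(method,
          time_shuffle = surrogate_time_shuffle(
            raw, config$n_surrogate_reps, config$detrend_order,
            config$pad_seconds, config$taper, config$fmin_hz, config$fmax_hz,
            seed = sseed
          ),
          random_accuracy = surrogate_random_accuracy(
            raw, config$n_surrogate_reps,
            detrend_order = config$detrend_order,
            pad_seconds = config$pad_seconds, taper = config$taper,
            fmin_hz = config$fmin_hz, fmax_hz = config$fmax_hz, seed = sseed
          ),
          ar_model = {
            fit <- fit_ar1(detrend_series(raw, config$detrend_order))
            surrogate_ar(
              fit, raw, config$n_surrogate_reps,
              detrend_order = config$detrend_order,
              pad_seconds = config$pad_seconds, taper = config$taper,
              fmin_hz = config$fmin_hz, fmax_hz = config$fmax_hz,
              seed = sseed
            )
          }
        )
      })
      reduce_surrogates(reps, reduce = config$surrogate_reduce)
    })
    sur_mat <- spectra_matrix(sur_subj)
    surrogates[[method]] <- sur_mat
    tests[[method]] <- stage("cluster_test", cluster_permutation_test(
      observed, sur_mat,
      n_permutations = config$n_permutations,
      alpha = config$alpha, tail = config$tail, method = method,
      seed = derive_seed(config$seed, paste("perm", method))
    ))
    say("%s: %d reps, %d permutations, %d cluster(s)", method,
        config$n_surrogate_reps, config$n_permutations,
        nrow(tests[[method]]$clusters))
  }

  manifest <- list(
    seed = config$seed,
    config_hash = fnv1a_hex(paste(utils::capture.output(
      utils::str(config[setdiff(names(config), c("trials", "out_dir"))])
    ), collapse = "\n")),
    n_trials = nrow(trials),
    n_subjects = length(subjects),
    n_sessions = length(sessions),
    n_clamped = attr(trials, "n_clamped") %||% NA_integer_,
    detrend_order = config$detrend_order,
    pad_seconds = config$pad_seconds,
    taper = config$taper$kind,
    smoothing_hz = config$taper$smoothing_hz,
    fmin_hz = config$fmin_hz, fmax_hz = config$fmax_hz,
    methods = config$methods,
    n_surrogate_reps = config$n_surrogate_reps,
    surrogate_reduce = config$surrogate_reduce,
    n_permutations = config$n_permutations,
    alpha = config$alpha, tail = config$tail,
    package_version = as.character(utils::packageVersion("behavosc")),
    log = log
  )

  res <- structure(
    list(
      trials = trials, series = series, observed = observed,
      group_spectrum = group_spectrum, surrogates = surrogates,
      tests = tests, manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d subjects, %d trials, methods: %s\n",
    x$manifest$n_subjects, x$manifest$n_trials,
    paste(names(x$tests), collapse = ", ")
  ))
  for (m in names(x$tests)) print(x$tests[[m]])
  invisible(x)
}

# CSV/JSON artefacts: spectra, surrogate reductions, cluster results,
# delay series, manifest. File contents depend only on the config and seed.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- attr(res$observed, "frequencies_hz")

  ser <- do.call(rbind, lapply(res$series, function(s) {
    data.frame(
      subject = s$subject, session = s$session, delay_ms = s$delays_ms,
      accuracy = s$accuracy, n_trials = s$n_trials, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(ser, file.path(out_dir, "delay_series.csv"),
                   row.names = FALSE)

  obs <- data.frame(
    subject = rep(rownames(res$observed), each = length(freqs)),
    frequency_hz = rep(freqs, times = nrow(res$observed)),
    power = as.vector(t(res$observed)), stringsAsFactors = FALSE
  )
  utils::write.csv(obs, file.path(out_dir, "observed_spectra.csv"),
                   row.names = FALSE)

  sur <- do.call(rbind, lapply(names(res$surrogates), function(m) {
    sm <- res$surrogates[[m]]
    data.frame(
      subject = rep(rownames(sm), each = length(freqs)),
      method = m,
      frequency_hz = rep(freqs, times = nrow(sm)),
      power = as.vector(t(sm)), stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(sur, file.path(out_dir, "surrogate_spectra.csv"),
                   row.names = FALSE)

  clusters <- lapply(res$tests, function(tst) {
    cl <- tst$clusters
    cl$method <- tst$method
    cl[c("freq_lo_hz", "freq_hi_hz", "cluster_stat", "p_value", "sign",
         "method")]
  })
  jsonlite::write_json(
    unname(clusters), file.path(out_dir, "clusters.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$manifest$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
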