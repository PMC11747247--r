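test_that("null generator produces chance-level accuracy at every delay", {
  cfg <- experiment_config(
    n_subjects = 1, n_sessions = 1, trials_per_delay = 2000,
    catch_rate = 0, control_trials_per_delay = 0, seed = 101
  )
  trials <- generate_experiment(cfg)
  s <- aggregate_accuracy(trials, "S01", 1)
  se <- sqrt(0.25 / 2000)
  expect_true(all(abs(s$accuracy - 0.5) < 3 * se))
  expect_equal(s$n_trials, rep(2000L, 19))
})

test_that("per-delay threshold trial counts are exact and conditions complete", {
  cfg <- experiment_config(n_subjects = 2, n_sessions = 2, seed = 102)
  trials <- generate_experiment(cfg)
  for (s in c("S01", "S02")) {
    for (k in 1:2) {
      ds <- aggregate_accuracy(trials, s, k)
      expect_equal(ds$n_trials, rep(20L, 19))
      expect_equal(length(ds$delays_ms), 19L)
    }
  }
  expect_setequal(
    unique(trials$soa_condition),
    c("short", "intermediate_minus", "threshold", "intermediate_plus",
      "long", "catch_real", "catch_fake")
  )
  # exactly one of correct / reported_seen populated per trial
  expect_true(all(xor(is.na(trials$correct), is.na(trials$reported_seen))))
  # catch trials carry no delay or SOA
  catch <- trials$soa_condition %in% c("catch_real", "catch_fake")
  expect_true(all(is.na(trials$delay_ms[catch])))
  expect_true(all(!is.na(trials$delay_ms[!catch])))
})

test_that("an injected 11 Hz component shows up in per-delay accuracy", {
  cfg <- experiment_config(
    n_subjects = 1, n_sessions = 1, trials_per_delay = 200,
    base_accuracy = 0.55, components = list(osc_component(11, 0.15)),
    catch_rate = 0, control_trials_per_delay = 0, seed = 103
  )
  trials <- generate_experiment(cfg)
  s <- aggregate_accuracy(trials, "S01", 1)
  target <- cosine_accuracy(11, 0.15, base = 0.55)
  expect_gt(cor(s$accuracy, target), 0.8)
})

test_that("catch rate and real:fake split match their binomial targets", {
  cfg <- experiment_config(
    n_subjects = 5, n_sessions = 2, trials_per_delay = 55,
    control_trials_per_delay = 0, catch_rate = 0.1, seed = 104
  )
  trials <- generate_experiment(cfg)
  n <- nrow(trials)
  is_catch <- trials$soa_condition %in% c("catch_real", "catch_fake")
  p_hat <- mean(is_catch)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  n_catch <- sum(is_catch)
  real_frac <- mean(trials$soa_condition[is_catch] == "catch_real")
  expect_lt(abs(real_frac - 0.5), 3 * sqrt(0.25 / n_catch))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- experiment_config(n_subjects = 3, n_sessions = 2, seed = 105)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a, b)
})

test_that("accuracy clamping is counted and probabilities stay in [0, 1]", {
  cfg <- experiment_config(
    n_subjects = 1, n_sessions = 1, base_accuracy = 0.9,
    components = list(osc_component(5, 0.3)), seed = 106
  )
  acc <- behavosc:::modulated_accuracy(cfg)
  expect_true(all(acc$p >= 0 & acc$p <= 1))
  expect_gt(acc$n_clamped, 0)
  trials <- generate_experiment(cfg)
  expect_equal(attr(trials, "n_clamped"), acc$n_clamped)
})

test_that("control conditions follow the observer's SOA psychometric", {
  obs <- observer_model(soa_threshold_ms = 42, soa_slope = 0.12)
  cfg <- experiment_config(
    n_subjects = 1, n_sessions = 1, trials_per_delay = 20,
    control_trials_per_delay = 40, catch_rate = 0, seed = 107
  )
  trials <- generate_experiment(cfg, obs)
  cs <- accuracy_by_condition(trials)
  ord <- c("short", "intermediate_minus", "threshold", "intermediate_plus",
           "long")
  expect_equal(as.character(cs$soa_condition), ord)
  # monotone decreasing accuracy from short to long SOA
  expect_true(all(diff(cs$mean_accuracy) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(experiment_config(delay_grid_ms = c(300, 290, 280)),
               "increasing")
  expect_error(experiment_config(delay_grid_ms = c(100, 120, 150)), "spaced")
  expect_error(experiment_config(catch_rate = 1))
  expect_error(osc_component(35, 0.1))
  expect_error(osc_component(11, 0.8))
})
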