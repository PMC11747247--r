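test_that("the cluster-forming threshold is the upper-tail t quantile", {
  expect_equal(round(t_critical(18, 0.05), 3), 1.734)
  expect_equal(t_critical(7, 0.5), 0)
  expect_equal(t_critical(1e6, 0.05), qnorm(0.95), tolerance = 1e-3)
  expect_error(t_critical(0, 0.05), "df")
})

test_that("paired t statistics per frequency match hand computation", {
  obs <- matrix(c(2, 3, 4), 3, 2)
  sur <- obs
  expect_equal(unname(paired_t_per_frequency(obs, sur)), c(0, 0),
               ignore_attr = TRUE)
  # differences [1, 2, 3]: t = 2 / (1 / sqrt(3)) = 2 * sqrt(3)
  sur2 <- obs - c(1, 2, 3)
  tv <- paired_t_per_frequency(obs, sur2)
  expect_equal(unname(tv), rep(2 * sqrt(3), 2), tolerance = 1e-12)
  # relabelling subjects leaves t unchanged
  perm <- c(3, 1, 2)
  tv_perm <- paired_t_per_frequency(obs[perm, ], sur2[perm, ])
  expect_equal(unname(tv_perm), unname(tv))
  # zero-variance differences yield signed infinity with a warning
  expect_warning(
    tz <- paired_t_per_frequency(matrix(2, 3, 1), matrix(1, 3, 1)),
    "zero variance"
  )
  expect_equal(unname(tz), Inf)
})

test_that("clusters are maximal suprathreshold runs with summed-t statistics", {
  thr <- 1.734
  expect_equal(nrow(form_clusters(c(0.2, 1.0, -1.0), thr)), 0)
  cl <- form_clusters(c(0, 2, 2, 0, 2), thr)
  expect_equal(cl$cluster_stat, c(4, 2))
  expect_equal(cl$lo_idx, c(2, 5))
  expect_equal(cl$hi_idx, c(3, 5))
  expect_equal(cl$sign, c("positive", "positive"))
  # singleton clusters allowed
  single <- form_clusters(c(0, 5, 0), thr)
  expect_equal(single$cluster_stat, 5)
  # negative clusters only in two-sided mode
  both <- form_clusters(c(-3, -3, 0, 2), thr, tail = "two_sided")
  expect_equal(both$cluster_stat, c(-6, 2))
  pos_only <- form_clusters(c(-3, -3, 0, 2), thr, tail = "one_sided_positive")
  expect_equal(pos_only$cluster_stat, 2)
  # frequency bookkeeping
  freqs <- 11:14
  cl2 <- form_clusters(c(2, 2, 0, 0), thr, frequencies_hz = freqs)
  expect_equal(cl2$freq_lo_hz, 11)
  expect_equal(cl2$freq_hi_hz, 12)
})

test_that("the permutation null is degenerate when observed equals surrogate", {
  set.seed(501)
  obs <- matrix(runif(5 * 4), 5, 4)
  null <- suppressWarnings(
    permutation_null(obs, obs, n_permutations = 200, threshold = 1.734,
                     tail = "one_sided_positive", seed = 1)
  )
  expect_equal(null$max_pos, rep(0, 200))
})

test_that("permutation null is seed-deterministic and warns past 2^n", {
  set.seed(502)
  obs <- matrix(runif(5 * 4), 5, 4)
  sur <- matrix(runif(5 * 4), 5, 4)
  expect_warning(
    a <- permutation_null(obs, sur, 100, threshold = 1.734, seed = 9),
    "2\\^n"
  )
  b <- suppressWarnings(
    permutation_null(obs, sur, 100, threshold = 1.734, seed = 9)
  )
  expect_identical(a, b)
})

test_that("sign-flip null matches a brute-force per-permutation t-test", {
  set.seed(503)
  n <- 6
  obs <- matrix(runif(n * 5), n, 5)
  sur <- matrix(runif(n * 5), n, 5)
  D <- obs - sur
  thr <- 1.5
  null <- suppressWarnings(
    permutation_null(obs, sur, 500, threshold = thr,
                     tail = "one_sided_positive", seed = 77)
  )
  # oracle: redraw the same sign matrix and loop over permutations
  oracle <- withr::with_seed(77, {
    S <- matrix(sample(c(-1, 1), 500 * n, replace = TRUE), 500, n)
    vapply(seq_len(500), function(i) {
      Df <- S[i, ] * D
      tv <- apply(Df, 2, function(col) {
        mean(col) / (sd(col) / sqrt(n))
      })
      cl <- form_clusters(tv, thr, tail = "one_sided_positive")
      if (nrow(cl) == 0) 0 else max(cl$cluster_stat)
    }, numeric(1))
  })
  expect_equal(null$max_pos, oracle, tolerance = 1e-10)
})

test_that("cluster p-values follow the +1-corrected rank formula", {
  clusters <- data.frame(
    freq_lo_hz = 10, freq_hi_hz = 12, lo_idx = 10, hi_idx = 12,
    cluster_stat = 50, sign = "positive"
  )
  null <- list(max_pos = rep(1, 999), min_neg = NULL, n_permutations = 999L)
  # larger than every null value
  expect_equal(cluster_p_values(clusters, null)$p_value, 1 / 1000)
  # zero statistic: every null value (all >= 0) counts
  clusters$cluster_stat <- 0
  expect_equal(cluster_p_values(clusters, null)$p_value, 1)
  # statistic at the null median: p about one half
  null2 <- list(max_pos = seq(0, 100, length.out = 1001), min_neg = NULL,
                n_permutations = 1001L)
  clusters$cluster_stat <- 50
  expect_equal(cluster_p_values(clusters, null2)$p_value, 0.5,
               tolerance = 2 / 1001)
})

test_that("enlarging observed power inside a cluster never raises its p-value", {
  set.seed(504)
  n <- 12
  obs <- matrix(rexp(n * 10), n, 10)
  obs[, 4:6] <- obs[, 4:6] + 1.5 # plant a positive cluster
  sur <- matrix(rexp(n * 10), n, 10)
  base <- cluster_permutation_test(
    obs, sur, n_permutations = 400, tail = "one_sided_positive", seed = 13
  )
  pos <- base$clusters[base$clusters$sign == "positive", ]
  expect_gt(nrow(pos), 0)
  target <- pos[which.max(pos$cluster_stat), ]
  for (bump in c(0.5, 2)) {
    obs2 <- obs
    obs2[, target$lo_idx:target$hi_idx] <-
      obs2[, target$lo_idx:target$hi_idx] + bump
    bumped <- cluster_permutation_test(
      obs2, sur, n_permutations = 400, tail = "one_sided_positive", seed = 13
    )
    pos2 <- bumped$clusters[
      bumped$clusters$lo_idx <= target$lo_idx &
        bumped$clusters$hi_idx >= target$hi_idx &
        bumped$clusters$sign == "positive", ]
    expect_equal(nrow(pos2), 1)
    expect_lte(pos2$p_value, target$p_value)
  }
})

test_that("p-values are invariant to subject relabelling", {
  set.seed(505)
  n <- 10
  obs <- matrix(rexp(n * 8) + rep(c(0, 2, 0), c(3, 2, 3))[col(matrix(0, n, 8))],
                n, 8)
  sur <- matrix(rexp(n * 8), n, 8)
  perm <- sample(n)
  a <- cluster_permutation_test(obs, sur, 300, tail = "one_sided_positive",
                                seed = 21)
  b <- cluster_permutation_test(obs[perm, ], sur[perm, ], 300,
                                tail = "one_sided_positive", seed = 21)
  expect_equal(a$clusters$cluster_stat, b$clusters$cluster_stat)
  # identical null law; with the same seed the sign matrix applies to
  # relabelled rows, so compare p-values up to Monte-Carlo tolerance
  expect_equal(a$clusters$p_value, b$clusters$p_value, tolerance = 0.1)
})
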