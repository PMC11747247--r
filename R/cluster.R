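#' Cluster-forming t threshold
#'
#' Upper-tail Student-t quantile used to threshold per-frequency t-values
#' before clustering. With 19 subjects (18 degrees of freedom) and
#' `alpha = 0.05` this is 1.734.
#'
#' @param df degrees of freedom, `>= 1`.
#' @param alpha upper-tail probability in `(0, 1)` (default 0.05).
#' @return The critical t value.
#' @export
t_critical <- function(df, alpha = 0.05) {
  if (!is_scalar_number(df) || df < 1) stop_invalid("df must be >= 1")
  stopifnot(is_scalar_number(alpha), alpha > 0, alpha < 1)
  stats::qt(1 - alpha, df)
}

as_power_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(spectra_matrix(x))
  stop_invalid("expected a matrix or a list of spectra")
}

#' Paired t-statistics per frequency
#'
#' For each frequency, the paired t statistic of the per-subject differences
#' observed minus surrogate, with `n - 1` degrees of freedom. A frequency
#' where the differences have zero variance yields a signed infinite t (0
#' when the mean difference is also 0) with a warning.
#'
#' @param observed,surrogate subjects-by-frequency matrices (or lists of
#'   spectra, stacked with [spectra_matrix()]); same subjects in the same
#'   order, same grid.
#' @return Named numeric vector of t values, one per frequency, with the
#'   frequency grid as the `frequencies_hz` attribute (when available).
#' @export
paired_t_per_frequency <- function(observed, surrogate) {
  obs <- as_power_matrix(observed)
  sur <- as_power_matrix(surrogate)
  if (!all(dim(obs) == dim(sur))) {
    stop_invalid("observed and surrogate must have identical dimensions")
  }
  n <- nrow(obs)
  if (n < 2) stop_invalid("need at least 2 subjects for a paired t-test")
  D <- obs - sur
  m <- colMeans(D)
  s <- apply(D, 2, stats::sd)
  tv <- numeric(length(m))
  zero <- s == 0
  if (any(zero & m != 0)) {
    warning("zero variance of paired differences at ", sum(zero & m != 0),
            " frequency bin(s); t reported as signed infinity")
  }
  tv[zero] <- sign(m[zero]) * Inf
  tv[zero & m == 0] <- 0 # identical conditions: no evidence either way
  tv[!zero] <- m[!zero] / (s[!zero] / sqrt(n))
  names(tv) <- colnames(obs)
  attr(tv, "frequencies_hz") <- attr(obs, "frequencies_hz")
  tv
}

#' Cluster contiguous suprathreshold frequencies
#'
#' Maximal runs of adjacent frequencies with `t > threshold` form positive
#' clusters; with `tail = "two_sided"`, runs with `t < -threshold`
#' additionally form negative clusters. A cluster's statistic is the sum of
#' its member t values; single-bin clusters are allowed.
#'
#' @param t_values per-frequency t statistics on a contiguous grid.
#' @param threshold positive cluster-forming threshold (e.g.
#'   [t_critical()]).
#' @param frequencies_hz optional frequency grid (default: the
#'   `frequencies_hz` attribute of `t_values`, else bin indices).
#' @param tail `"two_sided"` or `"one_sided_positive"`.
#' @return Data frame with one row per cluster: `freq_lo_hz`, `freq_hi_hz`,
#'   `lo_idx`, `hi_idx`, `cluster_stat`, `sign`.
#' @export
form_clusters <- function(t_values, threshold, frequencies_hz = NULL,
                          tail = c("two_sided", "one_sided_positive")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(t_values), is_scalar_number(threshold), threshold > 0)
  freqs <- frequencies_hz %||% attr(t_values, "frequencies_hz") %||%
    seq_along(t_values)
  out <- cluster_runs(t_values, threshold, freqs, "positive")
  if (tail == "two_sided") {
    out <- rbind(out, cluster_runs(-t_values, threshold, freqs, "negative"))
    if (nrow(out)) {
      out$cluster_stat <- ifelse(out$sign == "negative",
                                 -out$cluster_stat, out$cluster_stat)
      out <- out[order(out$lo_idx), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

# maximal runs of v > threshold; cluster_stat = sum of v in the run
cluster_runs <- function(v, threshold, freqs, sign_label) {
  above <- v > threshold
  empty <- data.frame(
    freq_lo_hz = numeric(0), freq_hi_hz = numeric(0),
    lo_idx = integer(0), hi_idx = integer(0),
    cluster_stat = numeric(0), sign = character(0),
    stringsAsFactors = FALSE
  )
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    freq_lo_hz = freqs[starts[keep]],
    freq_hi_hz = freqs[ends[keep]],
    lo_idx = starts[keep],
    hi_idx = ends[keep],
    cluster_stat = vapply(keep, function(i) sum(v[starts[i]:ends[i]]),
                          numeric(1)),
    sign = sign_label,
    stringsAsFactors = FALSE
  )
}

# largest positive-cluster sum of a t vector (0 when none above threshold)
max_cluster_stat <- function(tv, threshold) {
  above <- tv > threshold
  if (!any(above)) return(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(vapply(which(r$values), function(i) sum(tv[starts[i]:ends[i]]),
             numeric(1)))
}

#' Permutation null distribution of the largest cluster statistic
#'
#' Per permutation, each subject's observed and surrogate spectra are
#' independently swapped or kept — equivalently, the paired differences are
#' sign-flipped — the per-frequency t statistics are recomputed, clusters are
#' formed at the same threshold, and the largest cluster statistic is
#' recorded (0 when no cluster forms). Because sign flips leave the
#' per-subject squared differences unchanged, the whole null sample is
#' computed with closed-form matrix algebra rather than a per-permutation
#' t-test loop.
#'
#' @inheritParams paired_t_per_frequency
#' @param n_permutations number of random assignments (default 10000). When
#'   this exceeds the `2^n` distinct assignments a warning is issued and
#'   sampling proceeds with replacement.
#' @param threshold positive cluster-forming threshold.
#' @param tail `"two_sided"` records the most extreme negative cluster sum as
#'   well.
#' @param seed optional integer seed.
#' @return List with `max_pos` (length `n_permutations`), `min_neg` (or
#'   `NULL` for one-sided), `n_permutations`, `threshold`, `tail`.
#' @export
permutation_null <- function(observed, surrogate, n_permutations = 10000L,
                             threshold,
                             tail = c("two_sided", "one_sided_positive"),
                             seed = NULL) {
  tail <- match.arg(tail)
  obs <- as_power_matrix(observed)
  sur <- as_power_matrix(surrogate)
  if (!all(dim(obs) == dim(sur))) {
    stop_invalid("observed and surrogate must have identical dimensions")
  }
  n <- nrow(obs)
  if (n < 2) stop_invalid("need at least 2 subjects")
  if (!is_scalar_number(n_permutations) || n_permutations < 1) {
    stop_invalid("n_permutations must be at least 1")
  }
  if (n <= 30 && n_permutations > 2^n) {
    warning("n_permutations exceeds the 2^n distinct assignments; ",
            "sampling with replacement")
  }
  D <- obs - sur
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                n_permutations, n)
    M <- (S %*% D) / n
    css <- colSums(D^2)
    V <- pmax(sweep(-n * M^2, 2, css, "+") / (n - 1), 0)
    Tm <- M / sqrt(V / n)
    Tm[V == 0] <- ifelse(M[V == 0] == 0, 0, sign(M[V == 0]) * Inf)
    max_pos <- apply(Tm, 1, max_cluster_stat, threshold = threshold)
    min_neg <- if (tail == "two_sided") {
      -apply(-Tm, 1, max_cluster_stat, threshold = threshold)
    } else NULL
    list(
      max_pos = max_pos, min_neg = min_neg,
      n_permutations = as.integer(n_permutations),
      threshold = threshold, tail = tail
    )
  })
}

#' Permutation p-values for observed clusters
#'
#' Positive clusters are compared against the null sample of largest
#' positive cluster statistics: `p = (1 + #(null >= stat)) / (1 + B)`; the
#' "+1" guards the p-value away from zero and handles ties conservatively.
#' Negative clusters are mirrored against the most-negative-cluster null.
#'
#' @param clusters data frame from [form_clusters()].
#' @param null list from [permutation_null()].
#' @return `clusters` with a `p_value` column appended.
#' @export
cluster_p_values <- function(clusters, null) {
  stopifnot(is.data.frame(clusters), is.list(null))
  if (is.null(null$max_pos) || length(null$max_pos) == 0) {
    stop_invalid("empty null sample")
  }
  B <- null$n_permutations
  p <- vapply(seq_len(nrow(clusters)), function(i) {
    stat <- clusters$cluster_stat[i]
    if (clusters$sign[i] == "positive") {
      (1 + sum(null$max_pos >= stat)) / (1 + B)
    } else {
      if (is.null(null$min_neg)) {
        stop_invalid("negative cluster but one-sided null")
      }
      (1 + sum(null$min_neg <= stat)) / (1 + B)
    }
  }, numeric(1))
  clusters$p_value <- p
  clusters
}

#' Cluster-based permutation test of observed versus surrogate power
#'
#' End-to-end wrapper: per-frequency paired t statistics of observed minus
#' surrogate power, thresholding at `t_threshold` (by default the upper-tail
#' critical value [t_critical()]`(n - 1, alpha)`, i.e. 1.734 for 19
#' subjects), summed-t cluster statistics, and permutation p-values from
#' `n_permutations` random per-subject condition swaps with the
#' largest-cluster null.
#'
#' @inheritParams permutation_null
#' @param alpha cluster-forming tail probability (default 0.05).
#' @param t_threshold explicit threshold overriding `t_critical(n-1, alpha)`.
#' @param method optional label (surrogate method) carried into the result.
#' @return An object of class `cluster_test`: `clusters` (data frame with
#'   `freq_lo_hz`, `freq_hi_hz`, `cluster_stat`, `sign`, `p_value`),
#'   `t_values`, `frequencies_hz`, `threshold`, `tail`, `n_permutations`,
#'   `null`, `method`.
#' @export
cluster_permutation_test <- function(observed, surrogate,
                                     n_permutations = 10000L,
                                     alpha = 0.05,
                                     tail = c("two_sided",
                                              "one_sided_positive"),
                                     t_threshold = NULL,
                                     method = NA_character_,
                                     seed = NULL) {
  tail <- match.arg(tail)
  obs <- as_power_matrix(observed)
  sur <- as_power_matrix(surrogate)
  n <- nrow(obs)
  thr <- t_threshold %||% t_critical(n - 1, alpha)
  tv <- paired_t_per_frequency(obs, sur)
  freqs <- attr(obs, "frequencies_hz") %||% seq_len(ncol(obs))
  clusters <- form_clusters(tv, thr, frequencies_hz = freqs, tail = tail)
  null <- permutation_null(obs, sur, n_permutations = n_permutations,
                           threshold = thr, tail = tail, seed = seed)
  clusters <- cluster_p_values(clusters, null)
  structure(
    list(
      clusters = clusters, t_values = tv, frequencies_hz = freqs,
      threshold = thr, tail = tail,
      n_permutations = as.integer(n_permutations),
      null = null, method = method
    ),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> %s: threshold |t| > %.3f, %d permutations, %s\n",
    if (is.na(x$method)) "observed vs surrogate" else x$method,
    x$threshold, x$n_permutations, x$tail
  ))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf(
        "  %s cluster %g-%g Hz: stat %.2f, p = %.4g\n",
        cl$sign, cl$freq_lo_hz, cl$freq_hi_hz, cl$cluster_stat, cl$p_value
      ))
    }
  }
  invisible(x)
}
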