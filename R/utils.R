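#' Duration of one video frame in milliseconds
#'
#' The sampling step of the delay grid is one frame of a 60 Hz display.
#' Internally the exact value 1000/60 ms is used everywhere; 16.6 ms is its
#' conventional rounding.
#'
#' @return A single numeric, `1000/60`.
#' @export
frame_duration_ms <- function() 1000 / 60

#' Simple Weber contrast
#'
#' `weber_contrast()` is the classical definition
#' \eqn{(L - L_b)/L_b}; `midpoint_contrast()` is the symmetric variant
#' \eqn{2 (L - L_b)/(L + L_b)}. Both conversions between grey value and
#' contrast are in use for this stimulus bookkeeping: a 0.01 grey step on a
#' 0.38 background is a 2.6% step under the simple definition, while absolute
#' grey values such as 0.47 and 0.57 map to 21.2% and 40% under the
#' symmetric one.
#'
#' @param grey stimulus grey value (luminance proxy), `>= 0`.
#' @param background background grey value, `> 0` (default 0.38).
#' @return Contrast as a dimensionless fraction.
#' @export
weber_contrast <- function(grey, background = 0.38) {
  stopifnot(is.numeric(grey), is.numeric(background), background > 0)
  (grey - background) / background
}

#' @rdname weber_contrast
#' @export
midpoint_contrast <- function(grey, background = 0.38) {
  stopifnot(is.numeric(grey), is.numeric(background), (grey + background) > 0)
  2 * (grey - background) / (grey + background)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in [run_pipeline()] flows from one master seed; each stage
#' (generation, each surrogate method per subject and session, the
#' permutation test) draws its own stream seeded by
#' `derive_seed(master, label)`, so stages are independently reproducible.
#' The label is hashed with FNV-1a and folded into the seed modulo
#' 2^31 - 1, keeping the result a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((abs(seed) + h) %% (2^31 - 1))
}

# run code with a local RNG state when seed is given; leave the caller's
# RNG untouched either way if seed is NULL? No: if seed is NULL the caller's
# stream is consumed (documented behaviour, matches base R convention).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

# FNV-1a hash of a character scalar, hex string; used for config hashes in
# run manifests.
fnv1a_hex <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_invalid <- function(...) stop(..., call. = FALSE)
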