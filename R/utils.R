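# Internal utilities: canonical pair indexing, seed derivation, local RNG.

#' Canonical stimulus-pair index
#'
#' Returns the canonical ordering of unordered stimulus pairs used to
#' vectorize RDMs throughout the package: (1,2), (1,3), ..., (1,n),
#' (2,3), ..., (n-1,n). This is the column-major lower-triangle order of an
#' n x n matrix, i.e. the order produced by `stats::dist()` and by
#' `M[lower.tri(M)]`, so externally supplied RDM series interoperate as long
#' as they follow the same convention.
#'
#' @param n_stimuli number of stimuli (>= 2).
#' @return a data.frame with integer columns `i` and `j` (`i < j`), one row
#'   per pair, `n_stimuli * (n_stimuli - 1) / 2` rows in total.
#' @export
pair_index <- function(n_stimuli) {
  stopifnot(is.numeric(n_stimuli), length(n_stimuli) == 1, n_stimuli >= 2)
  n <- as.integer(n_stimuli)
  j <- rep(seq_len(n), each = n)   # column index of the square matrix
  i <- rep(seq_len(n), times = n)  # row index
  keep <- i > j                    # lower triangle, column-major
  data.frame(i = j[keep], j = i[keep])
}

#' Number of unordered pairs
#' @param n_stimuli number of stimuli.
#' @return `n_stimuli * (n_stimuli - 1) / 2` as an integer.
#' @export
n_pairs <- function(n_stimuli) {
  as.integer(n_stimuli * (n_stimuli - 1) / 2)
}

# Derive a child seed from a master seed and one or more integer keys.
# Deterministic, stays in [1, 2^31 - 2] so it is always a valid R seed.
# Adding stimuli/iterations/subjects never perturbs earlier streams because
# every unit draws from its own child seed.
child_seed <- function(seed, ...) {
  keys <- c(...)
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (abs(as.numeric(seed)) %% m)
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Smooth band-limited scalar signal: random-phase sinusoids on the Fourier
# grid of the window (multiples of 1/duration) at or below the cutoff.
# Tying frequencies to the window grid makes band-limitedness exact (no
# spectral leakage), so the periodogram invariant is testable at machine
# precision. With k = NULL (the default) every grid frequency in the band is
# used with a random amplitude — i.e. low-pass-filtered white noise, giving
# the trajectories a dense spectrum and hence temporally rich dissimilarity
# structure; an integer k instead draws k sparse grid frequencies.
band_limited_signal <- function(t, cutoff_hz, k = NULL, amplitude = 1) {
  duration <- length(t) * (t[2] - t[1])
  k_max <- max(1L, floor(cutoff_hz * duration))
  if (is.null(k)) {
    f <- seq_len(k_max) / duration
    a <- abs(stats::rnorm(k_max))
  } else {
    f <- sample.int(k_max, k, replace = TRUE) / duration
    a <- stats::runif(k, 0.3, 1)
  }
  a <- a / sqrt(sum(a^2)) * amplitude
  ph <- stats::runif(length(f), 0, 2 * pi)
  drop(sin(outer(t, 2 * pi * f) + rep(ph, each = length(t))) %*% a)
}

stop_param <- function(...) stop(..., call. = FALSE)
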