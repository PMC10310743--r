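# Time series of vectorized RDMs: the common currency of the pipeline.
# Values are [n_pairs x n_time] with pairs in the canonical order of
# pair_index(); the processing chain compute -> smooth -> rescale -> center
# is fixed and the applied steps are recorded on the object.

new_rdm_series <- function(values, n_stimuli, fs, metric, name,
                           steps = character(0)) {
  stopifnot(is.matrix(values), nrow(values) == n_pairs(n_stimuli))
  structure(list(values = values, n_stimuli = as.integer(n_stimuli), fs = fs,
                 metric = metric, name = name, steps = steps),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat("rdm_series '", x$name, "': ", nrow(x$values), " pairs (",
      x$n_stimuli, " stimuli) x ", ncol(x$values), " time points @ ",
      x$fs, " Hz, metric = ", x$metric,
      if (length(x$steps)) paste0(" [", paste(x$steps, collapse = " -> "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Compute a time series of RDMs from a feature model
#'
#' For every time point, pairwise dissimilarity between the stimulus feature
#' vectors under the model's metric (1 - Pearson correlation or Euclidean
#' distance), or under the model's pairwise rule when present (view-invariant
#' models). Pairs are vectorized in the canonical order of [pair_index()].
#'
#' Degenerate feature vectors (zero variance under the correlation metric)
#' yield NaN dissimilarities; these propagate with a reported count, and more
#' than 10% NaN entries is a hard error.
#'
#' @param model a `model_timeseries` with at least 3 stimuli.
#' @return an `rdm_series`.
#' @export
compute_rdm_series <- function(model) {
  stopifnot(inherits(model, "model_timeseries"))
  d <- dim(model$features)
  n_stim <- d[1]; n_time <- d[3]
  if (n_stim < 3) stop_param("need at least 3 stimuli for an RDM series")
  np <- n_pairs(n_stim)
  values <- matrix(NA_real_, np, n_time)
  pairs <- pair_index(n_stim)

  if (!is.null(model$pairwise_fun)) {
    for (t in seq_len(n_time)) {
      F <- model$features[, , t]
      values[, t] <- vapply(seq_len(np), function(p)
        model$pairwise_fun(F[pairs$i[p], ], F[pairs$j[p], ]), numeric(1))
    }
  } else if (model$metric == "one_minus_pearson") {
    for (t in seq_len(n_time)) {
      F <- model$features[, , t]
      C <- suppressWarnings(stats::cor(t(F)))
      values[, t] <- 1 - C[lower.tri(C)]
    }
  } else if (model$metric == "euclidean") {
    for (t in seq_len(n_time))
      values[, t] <- as.vector(stats::dist(model$features[, , t]))
  } else {
    stop_param("unknown metric: ", model$metric)
  }

  n_nan <- sum(!is.finite(values))
  if (n_nan > 0.10 * length(values))
    stop_param("more than 10% of dissimilarities are undefined (",
               n_nan, " of ", length(values), ")")
  if (n_nan > 0)
    message(n_nan, " undefined dissimilarities (degenerate feature vectors)",
            " propagated as NaN")
  new_rdm_series(values, n_stim, model$fs, model$metric, model$name)
}

#' Temporally smooth an RDM series with a boxcar kernel
#'
#' Per-pair moving average with a boxcar of `round(kernel_ms * fs / 1000)`
#' samples. Edge policy: the window shrinks (is truncated) at the series
#' boundaries, mirroring common M/EEG practice. NaN entries are excluded and
#' the window renormalized.
#'
#' @param r an `rdm_series`.
#' @param kernel_ms kernel length in milliseconds (>= 0; 0 or sub-sample
#'   lengths are the identity). Default 30 ms.
#' @return the smoothed `rdm_series` with `"smooth"` appended to its steps.
#' @export
smooth_rdm_series <- function(r, kernel_ms = 30) {
  stopifnot(inherits(r, "rdm_series"))
  if (kernel_ms < 0) stop_param("kernel_ms must be >= 0")
  n_time <- ncol(r$values)
  k <- max(1L, as.integer(round(kernel_ms * r$fs / 1000)))
  if (k > n_time) stop_param("smoothing kernel longer than the series")
  out <- r
  if (k > 1L) {
    offs <- -((k - 1L) %/% 2L):(k %/% 2L)
    acc <- matrix(0, nrow(r$values), n_time)
    cnt <- matrix(0, nrow(r$values), n_time)
    v <- r$values
    ok <- is.finite(v)
    v0 <- ifelse(ok, v, 0)
    for (o in offs) {
      src <- seq_len(n_time) + o
      valid <- src >= 1 & src <= n_time
      acc[, valid] <- acc[, valid] + v0[, src[valid], drop = FALSE]
      cnt[, valid] <- cnt[, valid] + ok[, src[valid], drop = FALSE]
    }
    out$values <- ifelse(cnt > 0, acc / cnt, NaN)
  }
  out$steps <- c(r$steps, "smooth")
  out
}

#' Min-max rescale an RDM series to the common 0-2 range
#'
#' One affine map over all pairs and time points at once, so the global
#' minimum becomes 0 and the global maximum 2 while per-timepoint relative
#' scale is preserved. Equalizes scales between metrics (Euclidean RDMs live
#' on an arbitrary scale, correlation RDMs on [0, 2]) before PCA/regression.
#'
#' @param r an `rdm_series`; must not be globally constant.
#' @return the rescaled `rdm_series` with `"rescale"` appended to its steps.
#' @export
rescale_rdm_series <- function(r) {
  stopifnot(inherits(r, "rdm_series"))
  rng <- range(r$values, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0)
    stop_param("cannot rescale a globally constant RDM series")
  out <- r
  out$values <- (r$values - rng[1]) / (rng[2] - rng[1]) * 2
  out$steps <- c(r$steps, "rescale")
  out
}

#' Center an RDM series per time point
#'
#' Subtracts the mean across pairs from every time slice, as required before
#' each PCA and regression step.
#'
#' @param r an `rdm_series`.
#' @return the centered `rdm_series` with `"center"` appended to its steps.
#' @export
center_columns <- function(r) {
  stopifnot(inherits(r, "rdm_series"))
  out <- r
  out$values <- sweep(r$values, 2, colMeans(r$values, na.rm = TRUE))
  out$steps <- c(r$steps, "center")
  out
}

#' Apply the canonical RDM preprocessing chain
#'
#' Fixed order: boxcar smoothing, then global min-max rescaling to 0-2, then
#' per-timepoint centering. The applied steps are recorded on the object and
#' asserted by the dRSA estimators.
#'
#' @param r an `rdm_series`.
#' @param kernel_ms boxcar length in milliseconds (default 30).
#' @return the prepared `rdm_series` (steps `smooth, rescale, center`).
#' @export
prepare_rdm_series <- function(r, kernel_ms = 30) {
  center_columns(rescale_rdm_series(smooth_rdm_series(r, kernel_ms)))
}

is_centered <- function(r, tol = 1e-8) {
  all(abs(colMeans(r$values, na.rm = TRUE)) < tol, na.rm = TRUE)
}

#' Expand one time slice of an RDM series into a square matrix
#'
#' @param r an `rdm_series`.
#' @param t time index.
#' @return a symmetric `n_stimuli x n_stimuli` matrix with zero diagonal.
#' @export
square_rdm <- function(r, t) {
  stopifnot(inherits(r, "rdm_series"), t >= 1, t <= ncol(r$values))
  n <- r$n_stimuli
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- r$values[, t]
  M + t(M)
}

#' Construct an RDM series from an external array
#'
#' Entry point for neural (or other externally computed) dissimilarity data:
#' the caller asserts that rows follow the canonical pair order of
#' [pair_index()].
#'
#' @param values numeric matrix `n_pairs x n_time`.
#' @param n_stimuli number of stimuli the pairs were built from.
#' @param fs sampling rate in Hz.
#' @param metric label describing the dissimilarity measure.
#' @param name label for the series.
#' @return an `rdm_series`.
#' @export
as_rdm_series <- function(values, n_stimuli, fs, metric = "external",
                          name = "neural") {
  new_rdm_series(as.matrix(values), n_stimuli, fs, metric, name)
}
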