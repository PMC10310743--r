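# The heart of the method: per (model-time, neural-time) similarity by
# principal component regression (PCR) with nuisance-model and
# autocorrelation control, 2D dRSA matrices, diagonal-averaged lag profiles,
# and the temporal subsampling-and-realignment loop.
#
# Lag sign convention (fixed project-wide): lag = t_neural - t_model.
# A positive-lag peak means the neural RDM follows the stimulus information
# (lagged representation); a negative-lag peak means the neural RDM predicts
# a future model state.

#' dRSA configuration
#'
#' Collects the tunable parameters of the dRSA estimator with their shipped
#' defaults: lag range +/- 1 s; 1000 subsampling iterations of 3-s segments;
#' first-stage PCA keeps components explaining at least 0.1% of a nuisance
#' block's total variance; the second PCA keeps at most the first 75
#' components (automatically bounded by the rank, i.e. by `n_pairs - 1`);
#' the test model's own time points are excluded from the nuisance set inside
#' the window where it shares at least 10% variance with itself.
#'
#' @param lag_range_s half-width of the lag window in seconds.
#' @param n_iterations number of subsampling iterations.
#' @param segment_s subsampled segment length in seconds.
#' @param var_threshold first-stage PCA variance fraction threshold.
#' @param max_components second-stage PCA component cap.
#' @param autocorr_r2_threshold shared-variance threshold defining the
#'   autocorrelation exclusion window.
#' @param kernel_ms boxcar smoothing kernel applied to RDM series.
#' @param seed master integer seed for all randomness downstream.
#' @return a list of class `drsa_config`.
#' @export
drsa_config <- function(lag_range_s = 1.0, n_iterations = 1000,
                        segment_s = 3.0, var_threshold = 0.001,
                        max_components = 75, autocorr_r2_threshold = 0.10,
                        kernel_ms = 30, seed = 1) {
  if (lag_range_s <= 0) stop_param("lag_range_s must be > 0")
  if (lag_range_s >= segment_s)
    stop_param("lag_range_s must be smaller than segment_s")
  if (n_iterations < 1) stop_param("n_iterations must be >= 1")
  if (var_threshold < 0 || var_threshold >= 1)
    stop_param("var_threshold must be in [0, 1)")
  if (max_components < 1) stop_param("max_components must be >= 1")
  structure(list(lag_range_s = lag_range_s, n_iterations = n_iterations,
                 segment_s = segment_s, var_threshold = var_threshold,
                 max_components = max_components,
                 autocorr_r2_threshold = autocorr_r2_threshold,
                 kernel_ms = kernel_ms, seed = as.integer(seed)),
            class = "drsa_config")
}

#' Autocorrelation exclusion window of an RDM series
#'
#' The smallest lag `delta` (in samples) at which the series shares less than
#' `threshold` of its variance with itself: the time-averaged squared Pearson
#' correlation between slices at `t` and `t + delta` drops below `threshold`.
#' When the test model itself enters the nuisance set of the PCR, its time
#' points within `+/- (delta - 1)` of the tested time point are excluded.
#' The window is computed once per series (time-averaged), not per time
#' point, for stability and speed.
#'
#' @param r an `rdm_series`.
#' @param threshold shared-variance fraction (default 0.10).
#' @return the window size in samples (integer >= 1). If the autocorrelation
#'   never drops below `threshold`, the series length is returned with a
#'   warning.
#' @export
autocorr_exclusion_window <- function(r, threshold = 0.10) {
  stopifnot(inherits(r, "rdm_series"))
  n_time <- ncol(r$values)
  if (n_time < 3) stop_param("series too short for an autocorrelation scan")
  C2 <- suppressWarnings(stats::cor(r$values))^2
  for (delta in seq_len(n_time - 1L)) {
    idx <- seq_len(n_time - delta)
    m <- mean(C2[cbind(idx, idx + delta)], na.rm = TRUE)
    if (is.finite(m) && m < threshold) return(as.integer(delta))
  }
  warning("autocorrelation never drops below ", threshold,
          "; exclusion window set to the series length")
  as.integer(n_time)
}

# First-stage PCA of one nuisance block [n_pairs x n_cols]: columns are
# time-point slices (already centered per time point); returns the component
# scores (U * d) for components explaining at least `var_threshold` of the
# block's total variance.
stage1_components <- function(block, var_threshold) {
  if (is.null(block) || ncol(block) == 0)
    return(matrix(0, nrow(block %||% matrix(0, 1, 0)), 0))
  block <- sweep(block, 2, colMeans(block))  # defensive re-centering
  s <- svd(block, nv = 0)
  tot <- sum(s$d^2)
  if (tot <= 0) return(matrix(0, nrow(block), 0))
  keep <- which(s$d^2 / tot >= var_threshold & s$d > 1e-12)
  if (!length(keep)) return(matrix(0, nrow(block), 0))
  s$u[, keep, drop = FALSE] %*% diag(s$d[keep], length(keep))
}

# Core of the PCR estimator. Given the (centered) test slice and the stacked
# first-stage nuisance components, runs the second PCA, keeps the first
# min(max_components, rank) components, and returns the weight vector w such
# that the back-projected regression coefficient of the test predictor for a
# neural slice y is sum(w * y). Returns NULL for a degenerate test slice.
pcr_weights <- function(test_slice, nuisance_scores, cfg) {
  if (stats::sd(test_slice) == 0) return(NULL)
  X <- cbind(nuisance_scores, test_slice, deparse.level = 0)
  X <- sweep(X, 2, colMeans(X))
  s <- svd(X)
  rank <- sum(s$d > max(s$d[1], 1e-300) * 1e-10)
  if (rank == 0) return(NULL)
  k <- min(cfg$max_components, rank)
  # gamma = D^-1 U' y ; beta = V gamma ; test coefficient = last row of V
  w <- s$u[, seq_len(k), drop = FALSE] %*%
    (s$v[ncol(X), seq_len(k)] / s$d[seq_len(k)])
  drop(w)
}

#' Principal-component-regression similarity for one cell
#'
#' Reference implementation of the per-cell PCR estimator: (1) a first-stage
#' PCA per nuisance block keeps components explaining at least
#' `cfg$var_threshold` of that block's variance; (2) the kept components are
#' stacked with the test slice and a second PCA keeps the first
#' `min(cfg$max_components, rank)` components (ordered by explained
#' variance); (3) the neural slice is regressed on those components by
#' least squares; (4) component coefficients are back-projected through the
#' second PCA's loadings onto the original predictors, and the coefficient
#' attached to the test slice is returned.
#'
#' @param neural_slice centered pair-vector at neural time `t_y`.
#' @param test_slice centered pair-vector of the test model at model time
#'   `t_x`.
#' @param nuisance_blocks list of matrices (`n_pairs x n_cols` each): other
#'   models at all time points, and the test model beyond its exclusion
#'   window.
#' @param cfg a [drsa_config()].
#' @return the back-projected regression weight for the test slice (NaN if
#'   the test slice has zero variance).
#' @export
pcr_similarity <- function(neural_slice, test_slice, nuisance_blocks = list(),
                           cfg = drsa_config()) {
  scores <- do.call(cbind, c(lapply(nuisance_blocks, stage1_components,
                                    var_threshold = cfg$var_threshold),
                             list(matrix(0, length(test_slice), 0))))
  w <- pcr_weights(test_slice, scores, cfg)
  if (is.null(w)) return(NaN)
  sum(w * neural_slice)
}

#' Compute the 2D dRSA matrix
#'
#' Similarity between the neural RDM series and the test model RDM series at
#' every (model time `t_x`, neural time `t_y`) pair within the lag band
#' `|t_y - t_x| <= lag_range_s` (cells outside the band are not computed and
#' stay NA).
#'
#' Estimators: `"pcr"` runs [pcr_similarity()] with all nuisance models (each
#' at all time points) plus the test model beyond its autocorrelation
#' exclusion window; `"correlation"` is the plain Pearson correlation between
#' slices, kept for comparison.
#'
#' All series must share sampling rate, pair count, length and the canonical
#' pair order, and must have been prepared (rescaled and centered; see
#' [prepare_rdm_series()]). Pairs with undefined values in any involved
#' series are dropped from all series (with a message) before estimation.
#'
#' @param neural the neural `rdm_series`.
#' @param test the test model `rdm_series`.
#' @param nuisance list of nuisance `rdm_series` (ignored by the correlation
#'   estimator).
#' @param cfg a [drsa_config()].
#' @param estimator `"pcr"` (default) or `"correlation"`.
#' @return an object of class `drsa_matrix`: list with `betas`
#'   (`n_time x n_time`, model time in rows, neural time in columns), `fs`,
#'   `estimator`, `test_model`, `lag_range_s`, and `exclusion_window`
#'   (samples; NA for the correlation estimator).
#' @export
drsa_matrix <- function(neural, test, nuisance = list(),
                        cfg = drsa_config(),
                        estimator = c("pcr", "correlation")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(neural, "rdm_series"), inherits(test, "rdm_series"))
  all_series <- c(list(neural, test), nuisance)
  if (length(unique(vapply(all_series, function(s) s$fs, numeric(1)))) != 1)
    stop_param("all series must share the sampling rate")
  if (length(unique(vapply(all_series, function(s) nrow(s$values), 1L))) != 1)
    stop_param("all series must share the number of pairs")
  if (length(unique(vapply(all_series, function(s) ncol(s$values), 1L))) != 1)
    stop_param("all series must share the number of time points")

  # drop pair rows with undefined entries anywhere, then re-center
  bad <- Reduce(`|`, lapply(all_series,
                            function(s) rowSums(!is.finite(s$values)) > 0))
  if (any(bad)) {
    message("dropping ", sum(bad), " pair rows with undefined values")
    drop_rows <- function(s) {
      s$values <- sweep(s$values[!bad, , drop = FALSE], 2,
                        colMeans(s$values[!bad, , drop = FALSE]))
      s
    }
    neural <- drop_rows(neural); test <- drop_rows(test)
    nuisance <- lapply(nuisance, drop_rows)
  }
  if (!is_centered(neural) || !is_centered(test))
    stop_param("series must be centered per time point before dRSA ",
               "(see prepare_rdm_series)")

  n_time <- ncol(test$values)
  L <- as.integer(round(cfg$lag_range_s * test$fs))
  if (L < 1) stop_param("lag range shorter than one sample")
  betas <- matrix(NA_real_, n_time, n_time)
  excl <- NA_integer_

  if (estimator == "correlation") {
    sds_t <- apply(test$values, 2, stats::sd)
    sds_n <- apply(neural$values, 2, stats::sd)
    Zt <- sweep(test$values, 2, ifelse(sds_t > 0, sds_t, NA), "/")
    Zn <- sweep(neural$values, 2, ifelse(sds_n > 0, sds_n, NA), "/")
    C <- crossprod(Zt, Zn) / (nrow(Zt) - 1)
    band <- abs(row(C) - col(C)) <= L
    betas[band] <- C[band]
  } else {
    excl <- autocorr_exclusion_window(test, cfg$autocorr_r2_threshold)
    nuis_scores <- do.call(cbind, c(list(matrix(0, nrow(test$values), 0)),
                                    lapply(nuisance, function(s)
                                      stage1_components(s$values,
                                                        cfg$var_threshold))))
    Y <- neural$values
    for (tx in seq_len(n_time)) {
      own <- test$values[, abs(seq_len(n_time) - tx) >= excl, drop = FALSE]
      own_scores <- stage1_components(own, cfg$var_threshold)
      w <- pcr_weights(test$values[, tx],
                       cbind(nuis_scores, own_scores), cfg)
      ty <- max(1L, tx - L):min(n_time, tx + L)
      betas[tx, ty] <- if (is.null(w)) NaN else drop(crossprod(w, Y[, ty]))
    }
  }
  structure(list(betas = betas, fs = test$fs, estimator = estimator,
                 test_model = test$name, lag_range_s = cfg$lag_range_s,
                 exclusion_window = excl),
            class = "drsa_matrix")
}

#' Average a dRSA matrix along the diagonal into a lag profile
#'
#' For every lag `l = t_neural - t_model` within `+/- lag_range_s`, averages
#' the matrix over all cells on the corresponding diagonal. All valid cells
#' inside the segment contribute (no fixed central window); `n_averaged`
#' reports how many cells entered each lag so that edge lags with less
#' support are visible.
#'
#' @param m a `drsa_matrix`.
#' @param lag_range_s half-width of the reported lag window (defaults to the
#'   matrix's own lag range).
#' @return an object of class `lag_profile`: list with `lags_s`, `values`,
#'   `n_averaged`, `fs`, `test_model`, `estimator`.
#' @export
lag_profile <- function(m, lag_range_s = m$lag_range_s) {
  stopifnot(inherits(m, "drsa_matrix"))
  n_time <- nrow(m$betas)
  L <- as.integer(round(lag_range_s * m$fs))
  if (L > n_time - 1) stop_param("lag range exceeds the matrix bounds")
  lags <- -L:L
  values <- numeric(length(lags))
  n_avg <- integer(length(lags))
  for (ii in seq_along(lags)) {
    l <- lags[ii]
    tx <- seq_len(n_time)
    ty <- tx + l
    ok <- ty >= 1 & ty <= n_time
    cells <- m$betas[cbind(tx[ok], ty[ok])]
    values[ii] <- mean(cells, na.rm = TRUE)
    n_avg[ii] <- sum(!is.na(cells))
  }
  structure(list(lags_s = lags / m$fs, values = values, n_averaged = n_avg,
                 fs = m$fs, test_model = m$test_model,
                 estimator = m$estimator),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  pk <- peak_lag(x)
  cat("lag_profile '", x$test_model, "' (", x$estimator, "): ",
      length(x$lags_s), " lags in [", min(x$lags_s), ", ", max(x$lags_s),
      "] s; peak ", signif(pk$value, 4), " at ", pk$lag_s, " s\n", sep = "")
  invisible(x)
}

#' Peak of a lag profile
#'
#' Highest value inside a lag window; ties break to the earliest lag.
#'
#' @param profile a `lag_profile` (or any list with `lags_s` and `values`).
#' @param window_s length-2 lag interval to search (default: whole range).
#' @return list with `lag_s` and `value`.
#' @export
peak_lag <- function(profile, window_s = range(profile$lags_s)) {
  sel <- which(profile$lags_s >= window_s[1] & profile$lags_s <= window_s[2] &
                 is.finite(profile$values))
  if (!length(sel)) stop_param("empty search window")
  i <- sel[which.max(profile$values[sel])]
  list(lag_s = profile$lags_s[i], value = profile$values[i])
}

#' Temporal subsampling, realignment and iteration-averaged dRSA
#'
#' The full dRSA loop: on every iteration a random segment of
#' `cfg$segment_s` seconds is extracted independently from each stimulus
#' (the same window for the neural stream and all models of that stimulus,
#' so their temporal alignment stays intact), the segments are realigned,
#' all RDM series are recomputed on the realigned segment (pairwise
#' alignment changes, so RDMs cannot be reused), and a dRSA matrix plus lag
#' profile is computed for every tested model with all other models as
#' nuisances. Profiles are averaged over iterations. Fully seed-determined
#' by `cfg$seed`.
#'
#' @param models named list of `model_timeseries`, all from one stimulus set.
#' @param neural one of: a `model_timeseries` holding per-stimulus neural
#'   feature patterns (subsampled and turned into RDMs like a model; RDM
#'   metric 1 - Pearson); an [implant_spec()] (a simulated neural series is
#'   built per iteration from the realigned, rescaled model RDMs); or an
#'   `rdm_series` (only allowed in the degenerate `segment_s == duration`
#'   case, since a pairwise series cannot be realigned per stimulus).
#' @param cfg a [drsa_config()].
#' @param estimator `"pcr"` or `"correlation"`.
#' @param test_models character vector of model names to test (default all).
#' @return named list of `lag_profile` objects (one per tested model), each
#'   carrying `n_iterations`; the attribute `"iteration_starts"` records the
#'   drawn window starts for provenance.
#' @export
drsa_subsample <- function(models, neural, cfg = drsa_config(),
                           estimator = c("pcr", "correlation"),
                           test_models = names(models)) {
  estimator <- match.arg(estimator)
  stopifnot(is.list(models), length(models) >= 1, !is.null(names(models)))
  stopifnot(all(test_models %in% names(models)))
  fs <- models[[1]]$fs
  n_time0 <- dim(models[[1]]$features)[3]
  n_stim <- dim(models[[1]]$features)[1]
  for (m in models)
    if (dim(m$features)[3] != n_time0 || dim(m$features)[1] != n_stim ||
        m$fs != fs)
      stop_param("all models must share stimuli, length and sampling rate")
  seg <- as.integer(round(cfg$segment_s * fs))
  if (seg > n_time0) stop_param("segment_s exceeds the stimulus duration")
  degenerate <- seg == n_time0
  if (degenerate && cfg$n_iterations > 1)
    message("segment equals the stimulus duration: single-pass dRSA")
  n_iter <- if (degenerate) 1L else cfg$n_iterations

  neural_mode <-
    if (inherits(neural, "model_timeseries")) "features"
    else if (inherits(neural, "implant_spec")) "implant"
    else if (inherits(neural, "rdm_series")) "rdm"
    else stop_param("unsupported neural input")
  if (neural_mode == "rdm" && !degenerate)
    stop_param("an external RDM series cannot be realigned per stimulus; ",
               "supply features or use segment_s == duration")

  acc <- list()
  starts_log <- matrix(NA_integer_, n_iter, n_stim)
  for (iter in seq_len(n_iter)) {
    starts <- if (degenerate) rep(1L, n_stim) else
      with_seed(child_seed(cfg$seed, 1000L, iter),
                sample.int(n_time0 - seg + 1L, n_stim, replace = TRUE))
    starts_log[iter, ] <- starts

    window_model <- function(m) {
      f <- m$features
      out <- array(NA_real_, c(n_stim, dim(f)[2], seg))
      for (s in seq_len(n_stim))
        out[s, , ] <- f[s, , starts[s] + seq_len(seg) - 1L]
      m$features <- out
      m
    }

    rescaled <- lapply(models, function(m)
      rescale_rdm_series(smooth_rdm_series(compute_rdm_series(window_model(m)),
                                           cfg$kernel_ms)))
    centered <- lapply(rescaled, center_columns)

    neural_series <- switch(neural_mode,
      features = {
        r <- compute_rdm_series(window_model(neural))
        center_columns(rescale_rdm_series(smooth_rdm_series(r, cfg$kernel_ms)))
      },
      implant = {
        spec_i <- neural
        spec_i$seed <- child_seed(neural$seed, 2000L, iter)
        center_columns(rescale_rdm_series(
          simulate_neural_rdm(rescaled, spec_i)))
      },
      rdm = prepare_rdm_series(neural, cfg$kernel_ms))

    for (tm in test_models) {
      mat <- drsa_matrix(neural_series, centered[[tm]],
                         nuisance = centered[names(centered) != tm],
                         cfg = cfg, estimator = estimator)
      prof <- lag_profile(mat)
      if (is.null(acc[[tm]])) {
        acc[[tm]] <- prof
        acc[[tm]]$values <- prof$values / n_iter
        acc[[tm]]$n_averaged <- as.numeric(prof$n_averaged) / n_iter
      } else {
        acc[[tm]]$values <- acc[[tm]]$values + prof$values / n_iter
        acc[[tm]]$n_averaged <- acc[[tm]]$n_averaged +
          as.numeric(prof$n_averaged) / n_iter
      }
    }
  }
  for (tm in test_models) acc[[tm]]$n_iterations <- n_iter
  attr(acc, "iteration_starts") <- starts_log
  acc
}
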