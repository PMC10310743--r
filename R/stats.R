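# Group-level inference and curve characterization: Fisher Z, one-sided
# cluster-based permutation tests on lag profiles, jackknifed peak latencies
# with single-subject retrieval, representational spread, and BH-FDR for
# map-style outputs.

#' Fisher Z transform
#'
#' Elementwise `atanh`. Regression weights can exceed +/- 1; such values are
#' clipped to just inside the open interval with a warning before
#' transforming, so the output stays finite.
#'
#' @param values numeric vector/matrix of similarity values.
#' @param clip_margin values are clipped to `+/- (1 - clip_margin)`.
#' @return transformed values, same shape.
#' @export
fisher_z <- function(values, clip_margin = 1e-7) {
  out <- values
  over <- is.finite(out) & abs(out) >= 1
  if (any(over)) {
    warning(sum(over), " values with |value| >= 1 clipped before atanh")
    out[over] <- sign(out[over]) * (1 - clip_margin)
  }
  atanh(out)
}

# maximum supra-threshold cluster mass of one t-curve (0 if none)
max_cluster_mass <- function(tvals, tcrit) {
  above <- tvals > tcrit
  if (!any(above)) return(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(vapply(which(r$values), function(i)
    sum(tvals[starts[i]:ends[i]]), numeric(1)))
}

#' Threshold presets for the cluster permutation test
#'
#' `"lenient"`: per-sample p < 0.01 with cluster-size p < 0.05;
#' `"strict"`: per-sample p < 0.001 with cluster-size p < 0.01.
#'
#' @param regime `"lenient"` or `"strict"`.
#' @return list with `sample_alpha` and `cluster_alpha`.
#' @export
cluster_thresholds <- function(regime = c("lenient", "strict")) {
  regime <- match.arg(regime)
  if (regime == "lenient") list(sample_alpha = 0.01, cluster_alpha = 0.05)
  else list(sample_alpha = 0.001, cluster_alpha = 0.01)
}

#' One-sided cluster-based permutation test on group lag profiles
#'
#' Per lag, a one-sample t statistic against zero (one-sided: greater).
#' Contiguous lags with per-sample p below `sample_alpha` form clusters whose
#' mass is the summed t. The null distribution of the maximum cluster mass is
#' built by randomly sign-flipping whole subject curves (the standard
#' one-sample scheme for within-subject effects); a cluster's p-value is the
#' fraction of null maxima at least as large as its mass (with the +1
#' correction), and clusters with p <= `cluster_alpha` are flagged.
#'
#' The permutation stream is tied to a canonical (lexicographic) ordering of
#' the subject curves, so p-values are invariant to the order in which
#' subjects are supplied.
#'
#' @param values numeric matrix `n_subjects x n_lags` (Fisher-Z lag
#'   profiles); no NA allowed.
#' @param lags_s optional lag grid in seconds (defaults to sample indices).
#' @param sample_alpha per-sample threshold (default 0.01).
#' @param cluster_alpha cluster-size threshold (default 0.05).
#' @param n_perm number of sign-flip permutations (default 25000).
#' @param seed integer seed for the sign flips.
#' @return a list of class `cluster_result`: `clusters` (data.frame with
#'   `start_lag`, `end_lag`, `mass`, `p_value`, `significant`),
#'   `sample_alpha`, `cluster_alpha`, `n_perm`, `t_values`, `t_critical`.
#' @export
cluster_permutation_test <- function(values, lags_s = NULL,
                                     sample_alpha = 0.01,
                                     cluster_alpha = 0.05,
                                     n_perm = 25000, seed = 1) {
  X <- as.matrix(values)
  n <- nrow(X); n_lags <- ncol(X)
  if (any(!is.finite(X))) stop_param("group profiles must be finite")
  if (n < 2) stop_param("need at least 2 subjects")
  if (n < 5) warning("fewer than 5 subjects: permutation distribution is coarse")
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  if (is.null(lags_s)) lags_s <- seq_len(n_lags)

  tcrit <- stats::qt(1 - sample_alpha, df = n - 1)
  ss <- colSums(X^2)  # invariant under sign flips
  t_of_means <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    ifelse(v > 0, m / sqrt(v / n), 0)
  }
  t_obs <- t_of_means(colMeans(X))

  # observed clusters
  above <- t_obs > tcrit
  clusters <- data.frame(start_lag = numeric(0), end_lag = numeric(0),
                         mass = numeric(0), p_value = numeric(0),
                         significant = logical(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ki <- which(r$values)
    # canonical subject order so results do not depend on input order
    ord <- do.call(order, as.data.frame(X))
    Xc <- X[ord, , drop = FALSE]
    null_max <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      M <- S %*% Xc / n
      V <- (matrix(ss, n_perm, n_lags, byrow = TRUE) - n * M^2) / (n - 1)
      Tm <- ifelse(V > 0, M / sqrt(V / n), 0)
      apply(Tm, 1, max_cluster_mass, tcrit = tcrit)
    })
    mass <- vapply(ki, function(i) sum(t_obs[starts[i]:ends[i]]), numeric(1))
    pv <- vapply(mass, function(m) (1 + sum(null_max >= m)) / (n_perm + 1),
                 numeric(1))
    clusters <- data.frame(start_lag = lags_s[starts[ki]],
                           end_lag = lags_s[ends[ki]],
                           mass = mass, p_value = pv,
                           significant = pv <= cluster_alpha)
  }
  structure(list(clusters = clusters, sample_alpha = sample_alpha,
                 cluster_alpha = cluster_alpha, n_perm = n_perm,
                 t_values = t_obs, t_critical = tcrit, lags_s = lags_s),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: sample alpha ", x$sample_alpha, ", cluster alpha ",
      x$cluster_alpha, ", ", x$n_perm, " permutations\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters) else cat("no clusters\n")
  invisible(x)
}

#' Jackknifed peak latency with single-subject retrieval
#'
#' Peak latencies of leave-one-subject-out average curves. Because each
#' jackknifed value averages `n - 1` subjects, its spread is artificially
#' small; single-subject estimates are retrieved as
#' `n * mean(jackknife) - (n - 1) * jackknife_i`, whose mean equals the grand
#' jackknife estimate by construction. Peaks are strict maxima (or minima for
#' `sign = "negative"`) on the discrete lag grid; ties break to the earliest
#' lag.
#'
#' @param values numeric matrix `n_subjects x n_lags` (>= 3 subjects).
#' @param lags_s lag grid in seconds.
#' @param search_window_s length-2 interval to search (must lie inside the
#'   lag range).
#' @param sign `"positive"` (search maxima, default) or `"negative"`
#'   (minima).
#' @return list with `grand_latency_s` (peak of the all-subject average),
#'   `jackknife_s`, `retrieved_s`, `mean_retrieved_s`, `search_window_s`.
#' @export
jackknife_peak_latency <- function(values, lags_s,
                                   search_window_s = range(lags_s),
                                   sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  X <- as.matrix(values)
  n <- nrow(X)
  if (n < 3) stop_param("need at least 3 subjects for jackknifing")
  if (search_window_s[1] < min(lags_s) || search_window_s[2] > max(lags_s))
    stop_param("search window outside the lag range")
  sel <- which(lags_s >= search_window_s[1] & lags_s <= search_window_s[2])

  find_peak <- function(curve) {
    v <- curve[sel]
    if (diff(range(v)) == 0)
      stop_param("flat curve in the search window: undefined peak")
    i <- if (sign == "positive") which.max(v) else which.min(v)
    lags_s[sel[i]]
  }
  grand <- find_peak(colMeans(X))
  jack <- vapply(seq_len(n), function(i) find_peak(colMeans(X[-i, , drop = FALSE])),
                 numeric(1))
  retrieved <- n * mean(jack) - (n - 1) * jack
  list(grand_latency_s = grand, jackknife_s = jack, retrieved_s = retrieved,
       mean_retrieved_s = mean(retrieved), search_window_s = search_window_s)
}

#' Representational spread
#'
#' Excess temporal width of an observed dRSA lag profile around its peak,
#' relative to what the model's own autocorrelation predicts. Both curves are
#' normalized by their (strictly positive) peak value, shifted so each peak
#' sits at distance 0, and subtracted (observed minus autocorrelation-only)
#' on the overlapping distance grid. The autocorrelation-only curve is the
#' lag profile of the full PCR pipeline run on a noise-free self-implant of
#' the model, capturing the pure effect of model autocorrelation. By
#' construction the spread at distance 0 is exactly 0; values near 1 indicate
#' a maximally sustained representation.
#'
#' @param observed a `lag_profile` (or list with `lags_s`, `values`, `fs`).
#' @param autocorr_only the matching autocorrelation-only `lag_profile`.
#' @return a list of class `rs_curve`: `distances_s` (signed distance from
#'   the peak), `rs`, `peak_lag_s` (observed peak latency).
#' @export
representational_spread <- function(observed, autocorr_only) {
  fs <- observed$fs %||% autocorr_only$fs
  norm_align <- function(p) {
    if (!length(p$values) || max(p$values, na.rm = TRUE) <= 0)
      stop_param("profile needs a strictly positive maximum")
    pk <- peak_lag(p)
    list(d = round((p$lags_s - pk$lag_s) * fs), v = p$values / pk$value)
  }
  o <- norm_align(observed)
  a <- norm_align(autocorr_only)
  common <- intersect(o$d, a$d)
  if (!length(common)) stop_param("no overlapping distances after alignment")
  common <- sort(common)
  rs <- o$v[match(common, o$d)] - a$v[match(common, a$d)]
  structure(list(distances_s = common / fs, rs = rs,
                 peak_lag_s = peak_lag(observed)$lag_s),
            class = "rs_curve")
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR control at level `q`; returns the significance mask.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical vector, TRUE where the hypothesis is rejected.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_param("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}
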