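# Stimulus-feature models. Each model is a `model_timeseries`: per-stimulus,
# per-timepoint feature vectors plus a dissimilarity metric, or additionally a
# pairwise rule when features cannot be compared directly (view-invariant
# models, which require Procrustes alignment per stimulus pair).

new_model_timeseries <- function(name, features, fs, metric,
                                 pairwise_fun = NULL) {
  stopifnot(length(dim(features)) == 3)
  if (any(!is.finite(features)))
    stop_param("non-finite values in model features for '", name, "'")
  structure(list(name = name, features = features, fs = fs, metric = metric,
                 pairwise_fun = pairwise_fun),
            class = "model_timeseries")
}

#' @export
print.model_timeseries <- function(x, ...) {
  d <- dim(x$features)
  cat("model_timeseries '", x$name, "': ", d[1], " stimuli x ", d[2],
      " features x ", d[3], " time points @ ", x$fs, " Hz, metric = ",
      x$metric, if (!is.null(x$pairwise_fun)) " (pairwise rule)", "\n",
      sep = "")
  invisible(x)
}

# ---- Gaussian smoothing -----------------------------------------------------

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Spatially smooth an image with an isotropic Gaussian
#'
#' Separable convolution with a kernel truncated at 4 sigma and replicate
#' (edge-extension) padding.
#'
#' @param img numeric matrix (height x width).
#' @param sigma Gaussian std in pixels (> 0).
#' @return smoothed matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) stop_param("sigma must be > 0")
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_dim <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    out <- m * 0
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- if (along == 1) m[idx, , drop = FALSE]
                 else m[, idx, drop = FALSE]
      out <- out + k[o + r + 1L] * shifted
    }
    out
  }
  conv_dim(conv_dim(img, 1), 2)
}

# ---- Pixelwise --------------------------------------------------------------

#' Pixelwise grayscale model
#'
#' Gaussian-smoothed luminance of every frame, vectorized: `H * W` features
#' per frame. Dissimilarity metric: 1 - Pearson correlation.
#'
#' @param frames a `frame_stack`.
#' @param sigma spatial smoothing std in pixels (default 5, the conventional
#'   low-pass for pixelwise RSA models).
#' @return a `model_timeseries` named `"pixelwise"`.
#' @export
pixelwise_model <- function(frames, sigma = 5) {
  stopifnot(inherits(frames, "frame_stack"))
  fr <- frames$frames
  d <- dim(fr)
  if (any(!is.finite(fr))) stop_param("non-finite values in frames")
  feats <- array(NA_real_, c(d[1], d[2] * d[3], d[4]))
  for (s in seq_len(d[1]))
    for (t in seq_len(d[4]))
      feats[s, , t] <- as.vector(gaussian_blur(fr[s, , , t], sigma))
  new_model_timeseries("pixelwise", feats, frames$fs, "one_minus_pearson")
}

# ---- Optical flow -----------------------------------------------------------

# Dense gradient-based flow between two frames: windowed (Lucas-Kanade style)
# local least squares on the brightness-constancy equation, with a small ridge
# so flat regions return zero flow instead of blowing up.
lk_flow <- function(f1, f2, window_sigma = 3) {
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
      pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
  }
  fm <- (f1 + f2) / 2
  ix <- (shift(fm, 0, 1) - shift(fm, 0, -1)) / 2   # d/dx, x = column
  iy <- (shift(fm, 1, 0) - shift(fm, -1, 0)) / 2   # d/dy, y = row
  it <- f2 - f1
  sxx <- gaussian_blur(ix * ix, window_sigma)
  sxy <- gaussian_blur(ix * iy, window_sigma)
  syy <- gaussian_blur(iy * iy, window_sigma)
  sxt <- gaussian_blur(ix * it, window_sigma)
  syt <- gaussian_blur(iy * it, window_sigma)
  eps <- 1e-6 * max(sxx + syy, 1e-12)
  det <- (sxx + eps) * (syy + eps) - sxy^2
  u <- (-sxt * (syy + eps) + sxy * syt) / det
  v <- (sxy * sxt - (sxx + eps) * syt) / det
  list(u = u, v = v)
}

#' Optical flow magnitude and direction models
#'
#' Dense per-pixel flow between consecutive frames (gradient-based local
#' least squares), spatially smoothed with the same Gaussian as the pixelwise
#' model, then split into a scalar magnitude model (`H * W` features) and a
#' raw 2D direction model (`2 * H * W` features: the u and v components,
#' unnormalized so zero flow stays well-defined). Flow between frames
#' `t-1` and `t` lives mid-way between them; like all derivative models it is
#' linearly interpolated back onto the original time grid with the first
#' sample duplicated from the second (see [motion_from_features()]).
#'
#' @param frames a `frame_stack` with at least 2 time points.
#' @param sigma spatial smoothing std in pixels.
#' @param window_sigma std of the Gaussian aggregation window of the flow
#'   estimator, in pixels.
#' @return list with elements `magnitude` and `direction`, both
#'   `model_timeseries` with metric 1 - Pearson.
#' @export
optical_flow_model <- function(frames, sigma = 5, window_sigma = 3) {
  stopifnot(inherits(frames, "frame_stack"))
  fr <- frames$frames
  d <- dim(fr)
  if (d[4] < 2) stop_param("optical flow needs at least 2 time points")
  npx <- d[2] * d[3]
  um <- array(NA_real_, c(d[1], npx, d[4] - 1L))
  vm <- um
  for (s in seq_len(d[1])) {
    for (t in 2:d[4]) {
      fl <- lk_flow(fr[s, , , t - 1], fr[s, , , t], window_sigma)
      um[s, , t - 1L] <- as.vector(gaussian_blur(fl$u, sigma))
      vm[s, , t - 1L] <- as.vector(gaussian_blur(fl$v, sigma))
    }
  }
  u <- midpoint_to_grid(um)
  v <- midpoint_to_grid(vm)
  mag <- sqrt(u^2 + v^2)
  dir <- array(NA_real_, c(d[1], 2L * npx, d[4]))
  dir[, seq_len(npx), ] <- u
  dir[, npx + seq_len(npx), ] <- v
  list(magnitude = new_model_timeseries("flow_magnitude", mag, frames$fs,
                                        "one_minus_pearson"),
       direction = new_model_timeseries("flow_direction", dir, frames$fs,
                                        "one_minus_pearson"))
}

# ---- Posture and motion -----------------------------------------------------

#' View-dependent body posture model
#'
#' Features are the flattened 3D marker coordinates in the common world frame
#' (3 * n_markers features per time point, marker-major order).
#'
#' @param traj a `marker_trajectories`.
#' @return a `model_timeseries` named `"posture_vd"`, metric 1 - Pearson.
#' @export
posture_view_dependent <- function(traj) {
  stopifnot(inherits(traj, "marker_trajectories"))
  pos <- traj$positions
  d <- dim(pos)
  feats <- array(NA_real_, c(d[1], d[2] * 3L, d[4]))
  for (m in seq_len(d[2]))
    for (cc in 1:3)
      feats[, (m - 1L) * 3L + cc, ] <- pos[, m, cc, ]
  new_model_timeseries("posture_vd", feats, traj$fs, "one_minus_pearson")
}

# Optimal rigid alignment of posture B onto posture A using 3D translation
# plus rotation about the vertical axis only (closed-form 2D Procrustes on
# the horizontal plane). Returns the aligned copy of B and the angle.
align_vertical <- function(A, B, vertical_axis = 3) {
  stopifnot(is.matrix(A), is.matrix(B), ncol(A) == 3, ncol(B) == 3,
            nrow(A) == nrow(B))
  if (nrow(A) < 2) stop_param("alignment needs at least 2 markers")
  h <- setdiff(1:3, vertical_axis)
  cA <- colMeans(A); cB <- colMeans(B)
  a <- sweep(A[, h, drop = FALSE], 2, cA[h])
  b <- sweep(B[, h, drop = FALSE], 2, cB[h])
  M <- crossprod(b, a)  # sum_m b_m a_m'
  theta <- atan2(M[1, 2] - M[2, 1], M[1, 1] + M[2, 2])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  B0 <- sweep(B, 2, cB)
  B0[, h] <- B0[, h] %*% t(R)
  list(aligned = sweep(B0, 2, cA, "+"), theta = theta, rotation = R)
}

one_minus_pearson <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NaN)
  1 - stats::cor(x, y)
}

#' View-invariant posture dissimilarity between two postures
#'
#' Aligns posture B to posture A by the optimal translation and rotation
#' about the vertical axis (closed-form constrained Procrustes, minimizing
#' the sum of squared marker differences), computes 1 - Pearson correlation
#' on the aligned coordinates, repeats in the opposite direction, and returns
#' the mean of the two dissimilarities (alignment direction matters, so both
#' are computed and averaged).
#'
#' @param posture_a,posture_b numeric vectors of length `3 * n_markers`
#'   (marker-major, as produced by [posture_view_dependent()]) or
#'   `n_markers x 3` matrices.
#' @param vertical_axis which coordinate is "up" (default 3).
#' @return a single dissimilarity in [0, 2] (NaN if a posture is degenerate).
#' @export
view_invariant_posture_dissim <- function(posture_a, posture_b,
                                          vertical_axis = 3) {
  as_mat <- function(p) {
    if (is.matrix(p)) return(p)
    if (length(p) %% 3 != 0) stop_param("posture length must be 3*n_markers")
    matrix(p, ncol = 3, byrow = TRUE)
  }
  A <- as_mat(posture_a); B <- as_mat(posture_b)
  d1 <- one_minus_pearson(as.vector(t(A)),
                          as.vector(t(align_vertical(A, B, vertical_axis)$aligned)))
  d2 <- one_minus_pearson(as.vector(t(B)),
                          as.vector(t(align_vertical(B, A, vertical_axis)$aligned)))
  (d1 + d2) / 2
}

#' View-invariant body posture model
#'
#' Same features as the view-dependent posture model, but dissimilarities are
#' computed by [view_invariant_posture_dissim()]: each stimulus pair is
#' Procrustes-aligned (translation + rotation about the vertical axis) in
#' both directions before correlating, so a pure rigid transform of the same
#' posture yields dissimilarity 0.
#'
#' @inheritParams posture_view_dependent
#' @param vertical_axis which coordinate is "up".
#' @return a `model_timeseries` named `"posture_vi"` carrying a pairwise rule.
#' @export
posture_view_invariant <- function(traj, vertical_axis = 3) {
  base <- posture_view_dependent(traj)
  rule <- function(fi, fj)
    view_invariant_posture_dissim(fi, fj, vertical_axis)
  new_model_timeseries("posture_vi", base$features, traj$fs,
                       "one_minus_pearson", pairwise_fun = rule)
}

# Resolve the half-sample shift of time derivatives: values computed between
# frames i-1 and i (i = 2..T) live at i - 0.5; linear interpolation back onto
# the integer grid gives the average of neighbouring midpoints for interior
# samples, the last midpoint at t = T, and the first output sample duplicated
# from the second, so all model series share one time grid.
midpoint_to_grid <- function(d) {
  # d: array [n_stim x n_feat x (T-1)], midpoint samples
  dd <- dim(d)
  out <- array(NA_real_, c(dd[1], dd[2], dd[3] + 1L))
  if (dd[3] >= 2) {
    out[, , 2:dd[3]] <- (d[, , 1:(dd[3] - 1), drop = FALSE] +
                           d[, , 2:dd[3], drop = FALSE]) / 2
  }
  out[, , dd[3] + 1L] <- d[, , dd[3]]
  out[, , 1L] <- if (dd[3] >= 2) out[, , 2L] else d[, , 1L]
  out
}

#' First temporal derivative of a feature model
#'
#' First difference along time (the motion of each feature between
#' consecutive frames), resolved back onto the original time grid by the
#' package's midpoint convention (see Details). Applying it to the posture
#' model gives view-dependent body motion; applying it twice gives
#' acceleration.
#'
#' @details The difference `x(i) - x(i-1)` conceptually lives mid-way between
#' frames `i-1` and `i`. The series is linearly interpolated back onto the
#' integer grid (interior samples become the mean of the two neighbouring
#' midpoints) and the first sample is duplicated from the second, keeping all
#' model series the same length.
#'
#' @param model a `model_timeseries` with at least 2 time points.
#' @param name optional name for the derived model (default appends `"_d1"`).
#' @return a `model_timeseries` with the same dimensions and metric.
#' @export
motion_from_features <- function(model, name = NULL) {
  stopifnot(inherits(model, "model_timeseries"))
  f <- model$features
  d <- dim(f)
  if (d[3] < 2) stop_param("need at least 2 time points for a derivative")
  dd <- f[, , 2:d[3], drop = FALSE] - f[, , 1:(d[3] - 1), drop = FALSE]
  new_model_timeseries(name %||% paste0(model$name, "_d1"),
                       midpoint_to_grid(dd), model$fs, model$metric)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' View-invariant body motion model
#'
#' Motion (first derivative of marker position, midpoint convention) compared
#' after view-invariant alignment: for a stimulus pair at time t, the
#' rotation that aligns one posture to the other about the vertical axis is
#' applied to the motion vectors (translation cancels in differences), then
#' 1 - Pearson is computed on the aligned motion; both alignment directions
#' are averaged.
#'
#' @inheritParams posture_view_invariant
#' @return a `model_timeseries` named `"motion_vi"` carrying a pairwise rule;
#'   its feature rows stack posture (first `3 * n_markers`) and motion (last
#'   `3 * n_markers`) coordinates, which the rule consumes.
#' @export
motion_view_invariant <- function(traj, vertical_axis = 3) {
  posture <- posture_view_dependent(traj)
  motion <- motion_from_features(posture)
  d <- dim(posture$features)
  feats <- array(NA_real_, c(d[1], 2L * d[2], d[3]))
  feats[, seq_len(d[2]), ] <- posture$features
  feats[, d[2] + seq_len(d[2]), ] <- motion$features
  np <- d[2]
  rule <- function(fi, fj) {
    Pi <- matrix(fi[seq_len(np)], ncol = 3, byrow = TRUE)
    Pj <- matrix(fj[seq_len(np)], ncol = 3, byrow = TRUE)
    Mi <- matrix(fi[np + seq_len(np)], ncol = 3, byrow = TRUE)
    Mj <- matrix(fj[np + seq_len(np)], ncol = 3, byrow = TRUE)
    h <- setdiff(1:3, vertical_axis)
    rot <- function(M, R) { M[, h] <- M[, h] %*% t(R); M }
    Rji <- align_vertical(Pi, Pj, vertical_axis)$rotation
    Rij <- align_vertical(Pj, Pi, vertical_axis)$rotation
    d1 <- one_minus_pearson(as.vector(t(Mi)), as.vector(t(rot(Mj, Rji))))
    d2 <- one_minus_pearson(as.vector(t(Mj)), as.vector(t(rot(Mi, Rij))))
    (d1 + d2) / 2
  }
  new_model_timeseries("motion_vi", feats, traj$fs, "one_minus_pearson",
                       pairwise_fun = rule)
}

#' Eye-position model
#'
#' Features are the four gaze channels (x, y for two eyes); dissimilarity is
#' the Euclidean distance between the four values — too few channels for a
#' reliable correlation estimate.
#'
#' @param gaze a `gaze_trace`.
#' @return a `model_timeseries` named `"gaze"`, metric `"euclidean"`.
#' @export
gaze_model <- function(gaze) {
  stopifnot(inherits(gaze, "gaze_trace"))
  new_model_timeseries("gaze", gaze$gaze, gaze$fs, "euclidean")
}

#' Build the standard stimulus-feature model battery
#'
#' Convenience constructor for the full model set from one synthetic stimulus
#' set: pixelwise, optical flow magnitude and direction, view-dependent and
#' view-invariant posture and motion, view-dependent acceleration, and eye
#' position. Any input that is NULL simply omits the dependent models.
#'
#' @param traj a `marker_trajectories` (required).
#' @param frames a `frame_stack` or NULL.
#' @param gaze a `gaze_trace` or NULL.
#' @param sigma spatial smoothing std in pixels for the video-based models.
#' @param include character vector of model names to keep (default all
#'   available).
#' @return named list of `model_timeseries`.
#' @export
model_battery <- function(traj, frames = NULL, gaze = NULL, sigma = 2,
                          include = NULL) {
  posture <- posture_view_dependent(traj)
  motion <- motion_from_features(posture, name = "motion_vd")
  out <- list(posture_vd = posture,
              posture_vi = posture_view_invariant(traj),
              motion_vd = motion,
              motion_vi = motion_view_invariant(traj),
              accel_vd = motion_from_features(motion, name = "accel_vd"))
  if (!is.null(frames)) {
    flow <- optical_flow_model(frames, sigma = sigma)
    out <- c(list(pixelwise = pixelwise_model(frames, sigma = sigma),
                  flow_magnitude = flow$magnitude,
                  flow_direction = flow$direction), out)
  }
  if (!is.null(gaze)) out$gaze <- gaze_model(gaze)
  if (!is.null(include)) {
    missing <- setdiff(include, names(out))
    if (length(missing))
      stop_param("unknown models requested: ", paste(missing, collapse = ", "))
    out <- out[include]
  }
  out
}
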