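# Synthetic stimulus generation: smooth marker kinematics, rendered grayscale
# frames, and gaze traces. The generator emulates the statistical structure of
# a motion-capture stimulus set (multiple stimuli, smooth band-limited motion,
# hierarchically correlated feature levels) without imitating any particular
# choreography. All units are arbitrary: every downstream dissimilarity is
# correlation-based or min-max rescaled, so physical scale is irrelevant.

#' Generate synthetic marker kinematics
#'
#' Produces per-stimulus 3D trajectories for a set of body markers. Each
#' marker trajectory is a fixed skeleton offset plus a whole-body component
#' shared by all markers of a stimulus plus a marker-specific component, all
#' sums of random-phase sinusoids with frequencies drawn strictly below
#' `cutoff_hz`, so the output is band-limited by construction. The shared
#' whole-body component is what makes rendered frames, posture and motion
#' models carry correlated variance, mirroring the feature hierarchy of real
#' action stimuli.
#'
#' Reproducibility: each stimulus draws from its own child RNG stream derived
#' from `seed`, so regenerating with a larger `n_stimuli` leaves earlier
#' stimuli bit-identical.
#'
#' @param n_stimuli number of stimuli (>= 3; an RDM needs at least 3 entries).
#' @param n_markers number of markers (>= 2).
#' @param duration_s stimulus duration in seconds; `duration_s * fs` must be
#'   a whole number of samples.
#' @param fs sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz maximal sinusoid frequency in Hz (default 2, a fixture
#'   choice for smooth whole-body movement).
#' @param seed master integer seed.
#' @param n_components number of sinusoids per signal; NULL (default) uses
#'   every Fourier-grid frequency in the band with random amplitudes
#'   (low-pass-filtered noise), an integer gives a sparse line spectrum.
#' @return an object of class `marker_trajectories`: list with `positions`
#'   (array `n_stimuli x n_markers x 3 x n_time`), `fs`, `cutoff_hz`,
#'   `stimulus_ids`.
#' @export
generate_kinematics <- function(n_stimuli, n_markers, duration_s, fs,
                                cutoff_hz = 2, seed = 1, n_components = NULL) {
  if (n_stimuli < 3) stop_param("n_stimuli must be >= 3")
  if (n_markers < 2) stop_param("n_markers must be >= 2")
  if (duration_s <= 0) stop_param("duration_s must be > 0")
  if (fs <= 2 * cutoff_hz) stop_param("fs must exceed 2 * cutoff_hz (Nyquist)")
  n_time <- duration_s * fs
  if (abs(n_time - round(n_time)) > 1e-8)
    stop_param("duration_s * fs must be an integer number of samples")
  n_time <- as.integer(round(n_time))
  tt <- (seq_len(n_time) - 1) / fs

  skeleton <- with_seed(child_seed(seed, 0L),
                        matrix(stats::runif(n_markers * 3, -1, 1), n_markers, 3))
  pos <- array(NA_real_, c(n_stimuli, n_markers, 3, n_time))
  for (s in seq_len(n_stimuli)) {
    with_seed(child_seed(seed, s), {
      global <- vapply(1:3, function(cc)
        band_limited_signal(tt, cutoff_hz, n_components, amplitude = 0.6),
        numeric(n_time))
      for (m in seq_len(n_markers)) {
        for (cc in 1:3) {
          idio <- band_limited_signal(tt, cutoff_hz, n_components,
                                      amplitude = 0.25)
          pos[s, m, cc, ] <- skeleton[m, cc] + global[, cc] + idio
        }
      }
    })
  }
  structure(list(positions = pos, fs = fs, cutoff_hz = cutoff_hz,
                 stimulus_ids = paste0("stim", seq_len(n_stimuli))),
            class = "marker_trajectories")
}

#' Render marker trajectories as grayscale frame stacks
#'
#' Orthographic projection: the depth axis is dropped, horizontal/vertical
#' marker coordinates are linearly scaled to fit 90% of the frame (one common
#' affine map for the whole stimulus set, so motion maps to pixel motion).
#' Each frame is the sum of isotropic Gaussian blobs (peak 1, std
#' `marker_sigma` pixels) at the projected marker positions, clipped to
#' [0, 1]. A marker projecting outside the frame raises a warning and is
#' clipped to the border, never an error.
#'
#' @param traj a `marker_trajectories` object.
#' @param height,width frame size in pixels.
#' @param marker_sigma Gaussian blob std in pixels.
#' @param vertical_axis which coordinate (1-3) is "up" (default 3); the
#'   remaining non-vertical axis is dropped as depth.
#' @return an object of class `frame_stack`: list with `frames` (array
#'   `n_stimuli x height x width x n_time`, values in [0, 1]) and `fs`.
#' @export
render_frames <- function(traj, height = 64, width = 60, marker_sigma = 2,
                          vertical_axis = 3) {
  stopifnot(inherits(traj, "marker_trajectories"))
  if (marker_sigma <= 0) stop_param("marker_sigma must be > 0")
  pos <- traj$positions
  d <- dim(pos)
  n_stim <- d[1]; n_mark <- d[2]; n_time <- d[4]
  horiz_axis <- setdiff(1:3, vertical_axis)[1]

  h <- pos[, , horiz_axis, , drop = FALSE]     # image x (width)
  v <- pos[, , vertical_axis, , drop = FALSE]  # image y (height)
  rng_h <- range(h); rng_v <- range(v)
  span <- function(r) max(r[2] - r[1], 1e-12)
  # common linear map into the central 90% of the frame
  px <- (h - rng_h[1]) / span(rng_h) * 0.9 * (width - 1) + 1 + 0.05 * (width - 1)
  py <- (rng_v[2] - v) / span(rng_v) * 0.9 * (height - 1) + 1 + 0.05 * (height - 1)
  out_of_frame <- px < 1 | px > width | py < 1 | py > height
  if (any(out_of_frame)) {
    warning(sum(out_of_frame), " projected marker positions fall outside the",
            " frame and were clipped to the border")
    px <- pmin(pmax(px, 1), width)
    py <- pmin(pmax(py, 1), height)
  }

  xs <- seq_len(width); ys <- seq_len(height)
  frames <- array(0, c(n_stim, height, width, n_time))
  for (s in seq_len(n_stim)) {
    acc <- array(0, c(height, width, n_time))
    for (m in seq_len(n_mark)) {
      # separable blob: outer product of 1D Gaussians, per time point
      ey <- exp(-outer(ys, py[s, m, 1, ], "-")^2 / (2 * marker_sigma^2))
      ex <- exp(-outer(xs, px[s, m, 1, ], "-")^2 / (2 * marker_sigma^2))
      for (t in seq_len(n_time))
        acc[, , t] <- acc[, , t] + tcrossprod(ey[, t], ex[, t])
    }
    frames[s, , , ] <- pmin(acc, 1)
  }
  structure(list(frames = frames, fs = traj$fs), class = "frame_stack")
}

#' Generate synthetic gaze traces
#'
#' Four smooth band-limited channels per stimulus (x and y position for two
#' eyes); the second eye follows the first up to a small independent
#' component, emulating binocular eye-tracker output under fixation.
#'
#' @inheritParams generate_kinematics
#' @return an object of class `gaze_trace`: list with `gaze` (array
#'   `n_stimuli x 4 x n_time`), `fs`, `cutoff_hz`.
#' @export
generate_gaze <- function(n_stimuli, duration_s, fs, seed = 1,
                          cutoff_hz = 2, n_components = NULL) {
  if (n_stimuli < 3) stop_param("n_stimuli must be >= 3")
  if (duration_s <= 0) stop_param("duration_s must be > 0")
  if (fs <= 2 * cutoff_hz) stop_param("fs must exceed 2 * cutoff_hz (Nyquist)")
  n_time <- duration_s * fs
  if (abs(n_time - round(n_time)) > 1e-8)
    stop_param("duration_s * fs must be an integer number of samples")
  n_time <- as.integer(round(n_time))
  tt <- (seq_len(n_time) - 1) / fs

  gaze <- array(NA_real_, c(n_stimuli, 4, n_time))
  for (s in seq_len(n_stimuli)) {
    with_seed(child_seed(seed, 7000L, s), {
      left_x <- band_limited_signal(tt, cutoff_hz, n_components, 1)
      left_y <- band_limited_signal(tt, cutoff_hz, n_components, 1)
      gaze[s, 1, ] <- left_x
      gaze[s, 2, ] <- left_y
      gaze[s, 3, ] <- left_x +
        band_limited_signal(tt, cutoff_hz, n_components, 0.1)
      gaze[s, 4, ] <- left_y +
        band_limited_signal(tt, cutoff_hz, n_components, 0.1)
    })
  }
  structure(list(gaze = gaze, fs = fs, cutoff_hz = cutoff_hz),
            class = "gaze_trace")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  d <- dim(x$positions)
  cat("marker_trajectories:", d[1], "stimuli x", d[2], "markers x 3 x",
      d[4], "time points @", x$fs, "Hz\n")
  invisible(x)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("frame_stack:", d[1], "stimuli x", d[2], "x", d[3], "px x",
      d[4], "time points @", x$fs, "Hz\n")
  invisible(x)
}
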