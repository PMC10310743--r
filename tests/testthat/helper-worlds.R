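# Shared fixture worlds, built in code on first use and cached for the run.
#
# The "acceptance" world is the scaled-down validation setting used by
# test-acceptance.R: 5 stimuli, 10 markers, 3-s stimuli at 50 Hz with a 6 Hz
# spectral cutoff (so model RDMs are temporally dynamic), 24 x 22 px frames,
# the 6-model battery, and a dRSA configuration with 2-s segments, 20
# subsampling iterations and a +/- 0.75 s lag window.

.world_cache <- new.env(parent = emptyenv())

acceptance_world <- function() {
  if (!is.null(.world_cache$acc)) return(.world_cache$acc)
  kin <- generate_kinematics(5, 10, 3, 50, cutoff_hz = 6, seed = 1)
  frames <- render_frames(kin, 24, 22, marker_sigma = 2)
  gaze <- generate_gaze(5, 3, 50, seed = 1, cutoff_hz = 6)
  models <- model_battery(kin, frames, gaze, sigma = 2,
                          include = c("pixelwise", "flow_magnitude",
                                      "flow_direction", "posture_vd",
                                      "motion_vd", "gaze"))
  cfg <- drsa_config(lag_range_s = 0.75, n_iterations = 20, segment_s = 2,
                     seed = 1)
  .world_cache$acc <- list(kin = kin, frames = frames, gaze = gaze,
                           models = models, cfg = cfg, fs = 50)
  .world_cache$acc
}

# a much smaller world for fast unit tests of the dRSA machinery
micro_world <- function() {
  if (!is.null(.world_cache$micro)) return(.world_cache$micro)
  kin <- generate_kinematics(4, 6, 2, 40, cutoff_hz = 5, seed = 11)
  posture <- posture_view_dependent(kin)
  motion <- motion_from_features(posture, name = "motion_vd")
  models <- list(posture_vd = posture, motion_vd = motion)
  rdms <- lapply(models, function(m)
    prepare_rdm_series(compute_rdm_series(m), kernel_ms = 30))
  .world_cache$micro <- list(kin = kin, models = models, rdms = rdms, fs = 40)
  .world_cache$micro
}

# independent periodogram-based band-power fraction (oracle for the
# band-limit invariant; uses stats::spec.pgram, not package code)
band_power_above <- function(x, fs, cutoff_hz) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  sum(sp$spec[sp$freq > cutoff_hz]) / sum(sp$spec)
}
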