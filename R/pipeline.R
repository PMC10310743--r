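# Configuration, persistence and the end-to-end workflow: simulate stimuli ->
# compute models -> compute RDMs -> simulate neural -> dRSA -> statistics.
# Archives are plain text: a JSON config/metadata file plus CSV matrices, with
# a format version checked on read.

ARCHIVE_FORMAT_VERSION <- "1.0"

#' Build a validated analysis configuration
#'
#' One document drives the whole pipeline; every run's output embeds the
#' fully resolved configuration (including the package version and all
#' seeds), and configurations round-trip losslessly through JSON.
#'
#' @param n_stimuli,n_markers,duration_s,fs,cutoff_hz stimulus-set
#'   parameters (see [generate_kinematics()]).
#' @param frame_height,frame_width,marker_sigma rendering parameters.
#' @param model_sigma spatial smoothing (px) of the video-based models.
#' @param models character vector of battery model names to compute.
#' @param implant_model,implant_lag_s,noise_weight neural simulation: which
#'   model to implant (default: first of `models`), at which lag, and the
#'   noise weight.
#' @param n_subjects number of simulated subjects for group statistics.
#' @param estimator `"pcr"` or `"correlation"`.
#' @param lag_range_s,segment_s,n_iterations,var_threshold,max_components,autocorr_r2_threshold,kernel_ms
#'   dRSA parameters (see [drsa_config()]).
#' @param sample_alpha,cluster_alpha,n_perm statistics thresholds.
#' @param seed master seed.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(n_stimuli = 5, n_markers = 8, duration_s = 2,
                            fs = 50, cutoff_hz = 2,
                            frame_height = 24, frame_width = 22,
                            marker_sigma = 2, model_sigma = 2,
                            models = c("pixelwise", "posture_vd", "motion_vd",
                                       "gaze"),
                            implant_model = NULL, implant_lag_s = 0,
                            noise_weight = 1, n_subjects = 6,
                            estimator = "pcr",
                            lag_range_s = 0.5, segment_s = 1.5,
                            n_iterations = 20, var_threshold = 0.001,
                            max_components = 75,
                            autocorr_r2_threshold = 0.10, kernel_ms = 30,
                            sample_alpha = 0.01, cluster_alpha = 0.05,
                            n_perm = 500, seed = 1) {
  cfg <- list(format_version = ARCHIVE_FORMAT_VERSION,
              package_version = as.character(utils::packageVersion("dynrsa")),
              n_stimuli = n_stimuli, n_markers = n_markers,
              duration_s = duration_s, fs = fs, cutoff_hz = cutoff_hz,
              frame_height = frame_height, frame_width = frame_width,
              marker_sigma = marker_sigma, model_sigma = model_sigma,
              models = models,
              implant_model = implant_model %||% models[[1]],
              implant_lag_s = implant_lag_s, noise_weight = noise_weight,
              n_subjects = n_subjects, estimator = estimator,
              lag_range_s = lag_range_s, segment_s = segment_s,
              n_iterations = n_iterations, var_threshold = var_threshold,
              max_components = max_components,
              autocorr_r2_threshold = autocorr_r2_threshold,
              kernel_ms = kernel_ms, sample_alpha = sample_alpha,
              cluster_alpha = cluster_alpha, n_perm = n_perm,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  num_fields <- c("n_stimuli", "n_markers", "duration_s", "fs", "cutoff_hz",
                  "frame_height", "frame_width", "marker_sigma",
                  "model_sigma", "implant_lag_s", "noise_weight",
                  "n_subjects", "lag_range_s", "segment_s", "n_iterations",
                  "var_threshold", "max_components",
                  "autocorr_r2_threshold", "kernel_ms", "sample_alpha",
                  "cluster_alpha", "n_perm", "seed")
  for (f in num_fields)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]))
      stop_param("config field '", f, "' must be a single finite number")
  if (cfg$segment_s > cfg$duration_s)
    stop_param("segment_s cannot exceed duration_s")
  if (cfg$lag_range_s >= cfg$segment_s)
    stop_param("lag_range_s must be smaller than segment_s")
  if (!cfg$estimator %in% c("pcr", "correlation"))
    stop_param("estimator must be 'pcr' or 'correlation'")
  invisible(cfg)
}

#' Write / read an analysis configuration as JSON
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` is identical
#' to `cfg`. Readers reject archives with an unknown major format version.
#'
#' @param cfg an `analysis_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  major <- strsplit(as.character(cfg$format_version %||% "0"), "[.]")[[1]][1]
  if (major != strsplit(ARCHIVE_FORMAT_VERSION, "[.]")[[1]][1])
    stop_param("unsupported archive format version: ", cfg$format_version)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Run the end-to-end dRSA pipeline
#'
#' Executes simulate-stimuli -> compute-models -> compute-RDMs ->
#' simulate-neural -> subsampled dRSA -> group statistics, writing a
#' plain-text archive (JSON config echo, CSV matrices, per-stage timing log)
#' to `out_dir`. Deterministic: rerunning with the same configuration
#' reproduces bit-identical outputs. If the RDM CSVs of a previous run were
#' deleted they are simply recomputed; downstream outputs are unchanged.
#'
#' @param cfg an [analysis_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with `config`, `rdms`, `profiles` (per-subject
#'   lag profiles of the implanted model), `group_values`, `clusters`,
#'   `timings_s`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "analysis_config"))
  validate_config(cfg)
  timings <- c()
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    line <- sprintf("stage %-16s %8.2f s", name, dt)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    res
  }

  stim <- stage("stimuli", {
    kin <- generate_kinematics(cfg$n_stimuli, cfg$n_markers, cfg$duration_s,
                               cfg$fs, cfg$cutoff_hz, seed = cfg$seed)
    frames <- if (any(c("pixelwise", "flow_magnitude", "flow_direction")
                      %in% cfg$models))
      render_frames(kin, cfg$frame_height, cfg$frame_width, cfg$marker_sigma)
    gaze <- if ("gaze" %in% cfg$models)
      generate_gaze(cfg$n_stimuli, cfg$duration_s, cfg$fs,
                    seed = child_seed(cfg$seed, 11L), cfg$cutoff_hz)
    list(kin = kin, frames = frames, gaze = gaze)
  })
  models <- stage("models",
    model_battery(stim$kin, stim$frames, stim$gaze, sigma = cfg$model_sigma,
                  include = cfg$models))
  rdms <- stage("rdms", lapply(models, function(m)
    rescale_rdm_series(smooth_rdm_series(compute_rdm_series(m),
                                         cfg$kernel_ms))))

  dcfg <- drsa_config(lag_range_s = cfg$lag_range_s,
                      n_iterations = cfg$n_iterations,
                      segment_s = cfg$segment_s,
                      var_threshold = cfg$var_threshold,
                      max_components = cfg$max_components,
                      autocorr_r2_threshold = cfg$autocorr_r2_threshold,
                      kernel_ms = cfg$kernel_ms, seed = cfg$seed)

  profiles <- stage("drsa", {
    lapply(seq_len(cfg$n_subjects), function(subj) {
      spec <- implant_spec(list(implant(cfg$implant_model, 1,
                                        cfg$implant_lag_s)),
                           noise_weight = cfg$noise_weight,
                           seed = child_seed(cfg$seed, 5000L, subj))
      drsa_subsample(models, spec, dcfg, estimator = cfg$estimator,
                     test_models = cfg$implant_model)[[cfg$implant_model]]
    })
  })

  stats_out <- stage("stats", {
    group <- do.call(rbind, lapply(profiles, function(p) p$values))
    groupz <- suppressWarnings(fisher_z(group))
    cluster_permutation_test(groupz, lags_s = profiles[[1]]$lags_s,
                             sample_alpha = cfg$sample_alpha,
                             cluster_alpha = cfg$cluster_alpha,
                             n_perm = cfg$n_perm,
                             seed = child_seed(cfg$seed, 6000L))
  })

  result <- list(config = cfg, rdms = rdms, profiles = profiles,
                 group_values = do.call(rbind,
                                        lapply(profiles, function(p) p$values)),
                 clusters = stats_out, timings_s = timings)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "rdms"), showWarnings = FALSE)
    write_config(cfg, file.path(out_dir, "config.json"))
    for (nm in names(rdms))
      write_matrix_csv(rdms[[nm]]$values,
                       file.path(out_dir, "rdms", paste0(nm, ".csv")))
    prof_tab <- do.call(rbind, lapply(seq_along(profiles), function(i)
      data.frame(subject = i, lag_s = profiles[[i]]$lags_s,
                 value = profiles[[i]]$values,
                 n_averaged = profiles[[i]]$n_averaged)))
    utils::write.csv(prof_tab, file.path(out_dir, "lag_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_out$clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    writeLines(c(paste("dynrsa archive, format", ARCHIVE_FORMAT_VERSION),
                 log_lines), file.path(out_dir, "log.txt"))
  }
  invisible(result)
}

#' Demo configuration
#'
#' A small end-to-end configuration (5 stimuli, 8 markers, 2-s stimuli at
#' 50 Hz, 20 subsampling iterations) that exercises every pipeline stage in
#' well under a minute.
#'
#' @param seed master seed.
#' @return an [analysis_config()].
#' @export
demo_config <- function(seed = 1) {
  analysis_config(seed = seed)
}
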