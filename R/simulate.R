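# Simulated "neural" RDM series: weighted, lag-shifted model RDM series plus
# temporally white uniform noise. The engine behind the package's parameter-
# recovery validation (single-model implants, combined implants, noise
# sweeps).

#' Specify a simulated neural RDM series
#'
#' @param components list of implant components, each a list (or the output
#'   of [implant()]) with fields `model` (name matching the model list),
#'   `weight` (>= 0) and `lag_s` (seconds; positive lag = the neural series
#'   follows the model, i.e. a lagged representation).
#' @param noise_weight weight of the uniform noise series (>= 0). At least
#'   one component or a positive noise weight is required.
#' @param seed integer seed for the noise draws.
#' @return a list of class `implant_spec`.
#' @export
implant_spec <- function(components = list(), noise_weight = 0, seed = 1) {
  if (length(components) && !is.null(components$model))
    components <- list(components)  # single component given directly
  for (cmp in components) {
    if (is.null(cmp$model) || is.null(cmp$weight) || is.null(cmp$lag_s))
      stop_param("each component needs model, weight and lag_s")
    if (!is.finite(cmp$weight) || cmp$weight < 0)
      stop_param("component weights must be finite and >= 0")
  }
  if (noise_weight < 0 || !is.finite(noise_weight))
    stop_param("noise_weight must be finite and >= 0")
  if (!length(components) && noise_weight == 0)
    stop_param("need at least one component or a positive noise weight")
  structure(list(components = components, noise_weight = noise_weight,
                 seed = as.integer(seed)),
            class = "implant_spec")
}

#' @rdname implant_spec
#' @param model model name.
#' @param weight implant weight.
#' @param lag_s implant lag in seconds.
#' @export
implant <- function(model, weight = 1, lag_s = 0) {
  list(model = model, weight = weight, lag_s = lag_s)
}

#' Simulate a neural RDM series by implanting model RDM series
#'
#' The output at time `t` is the weighted sum of each implanted model's RDM
#' slice at `t - round(lag_s * fs)` plus `noise_weight` times a temporally
#' white uniform noise series. Noise is drawn from U(0, 2) to match the
#' common rescaled RDM range (the distribution family is fixed, the support
#' is a package choice). Samples shifted in from beyond the series edge are
#' filled with fresh uniform noise at the same component weight, keeping the
#' output the same length as its inputs. Non-integer lag offsets are rounded,
#' not interpolated: RDM slices are not band-limited objects.
#'
#' @param models named list of `rdm_series`, time-aligned and rescaled to the
#'   common 0-2 range (see [rescale_rdm_series()]).
#' @param spec an [implant_spec()].
#' @return an `rdm_series` named `"neural_sim"`. Deterministic given
#'   `spec$seed`.
#' @export
simulate_neural_rdm <- function(models, spec) {
  stopifnot(inherits(spec, "implant_spec"), is.list(models),
            length(models) >= 1)
  ref <- models[[1]]
  np <- nrow(ref$values); n_time <- ncol(ref$values); fs <- ref$fs
  for (m in models)
    if (nrow(m$values) != np || ncol(m$values) != n_time || m$fs != fs)
      stop_param("all model series must be time-aligned with equal pairs")

  with_seed(spec$seed, {
    out <- matrix(0, np, n_time)
    for (cmp in spec$components) {
      if (!cmp$model %in% names(models))
        stop_param("unknown implant model: ", cmp$model)
      k <- as.integer(round(cmp$lag_s * fs))
      if (abs(k) >= n_time)
        stop_param("implant lag shift exceeds the series length")
      src <- seq_len(n_time) - k
      valid <- src >= 1 & src <= n_time
      out[, valid] <- out[, valid] +
        cmp$weight * models[[cmp$model]]$values[, src[valid], drop = FALSE]
      if (any(!valid))
        out[, !valid] <- out[, !valid] +
          cmp$weight * matrix(stats::runif(np * sum(!valid), 0, 2),
                              np, sum(!valid))
    }
    if (spec$noise_weight > 0)
      out <- out + spec$noise_weight *
        matrix(stats::runif(np * n_time, 0, 2), np, n_time)
    new_rdm_series(out, ref$n_stimuli, fs, "simulated", "neural_sim")
  })
}

#' Simulate a group of subjects with identical implants
#'
#' Each subject gets an independent noise stream (child seed per subject)
#' while the implant components are identical, emulating a group sharing one
#' true representational structure.
#'
#' @inheritParams simulate_neural_rdm
#' @param n_subjects number of simulated subjects.
#' @return list of `rdm_series`, one per subject.
#' @export
simulate_neural_subjects <- function(models, spec, n_subjects) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(subj) {
    sp <- spec
    sp$seed <- child_seed(spec$seed, 3000L, subj)
    simulate_neural_rdm(models, sp)
  })
}

#' Preset implant-to-noise ratios
#'
#' The standard noise sweep: implant-to-noise ratios 1:0, 1:1, 1:5 and 1:10.
#'
#' @param model model name to implant (weight 1, lag 0).
#' @param seed integer seed.
#' @return named list of [implant_spec()] objects
#'   (`"1:0"`, `"1:1"`, `"1:5"`, `"1:10"`).
#' @export
noise_ratio_presets <- function(model, seed = 1) {
  ratios <- c(0, 1, 5, 10)
  out <- lapply(seq_along(ratios), function(i)
    implant_spec(list(implant(model, 1, 0)), noise_weight = ratios[i],
                 seed = child_seed(seed, 4000L, i)))
  names(out) <- paste0("1:", ratios)
  out
}
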