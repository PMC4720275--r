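#' Simulation configuration for synthetic auditory ERP data
#'
#' Collects the knobs of the synthetic data generator.  The generator
#' emulates the morphology of an auditory N100: a Gaussian deflection in
#' time (deliberately not a Mexican hat, so the wavelet detector is not
#' trivially matched to the signal), negative over fronto-central channels
#' and positive over temporal channels, superimposed on pink (1/f)
#' background noise.
#'
#' `effect_scale` controls how strongly the twelve stimulus conditions
#' differ: 0 makes all condition templates identical (a null dataset); 1 is
#' the package default (20 ms latency spread, 50% amplitude-gain spread and
#' a 20 degree topography-azimuth spread across the four frequencies, plus a
#' binaural gain boost and contralateral topography tilt for monaural
#' stimulation).  It may be a single number or a named per-modality vector,
#' e.g. `c(left = 1, right = 0, binaural = 1)` to inject frequency effects
#' only into trials in which the left ear was stimulated.
#'
#' @param n_channels number of scalp channels (63 = full analysis montage,
#'   16 = reduced test profile; see [montage_subset()])
#' @param fs_hz sampling frequency, Hz (the pipeline assumes 1000)
#' @param trials_per_condition presentations per stimulus type used when no
#'   protocol is supplied to [simulate_epochs()]
#' @param noise_sd_uV per-channel pink-noise standard deviation, microvolts
#' @param effect_scale scalar or named per-modality vector, see Details
#' @param latency_shift_ms,amplitude_gain,topography_rot_deg length-4
#'   per-frequency perturbations applied in proportion to `effect_scale`
#'   (order 250, 500, 1000, 2000 Hz)
#' @param modality_gain,modality_rot_deg named length-3 per-modality
#'   perturbations, also scaled by `effect_scale`
#' @param seed integer RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_channels = 63, fs_hz = 1000,
                       trials_per_condition = 200, noise_sd_uV = 5,
                       effect_scale = 1,
                       latency_shift_ms = c(-10, -10 / 3, 10 / 3, 10),
                       amplitude_gain = c(-0.25, -1 / 12, 1 / 12, 0.25),
                       topography_rot_deg = c(-10, -10 / 3, 10 / 3, 10),
                       modality_gain = c(left = 0, right = 0, binaural = 0.15),
                       modality_rot_deg = c(left = 8, right = -8, binaural = 0),
                       seed = 1) {
  stopifnot(fs_hz > 0, noise_sd_uV >= 0, all(effect_scale >= 0),
            length(latency_shift_ms) == 4, length(amplitude_gain) == 4,
            length(topography_rot_deg) == 4)
  structure(list(n_channels = n_channels, fs_hz = fs_hz,
                 trials_per_condition = trials_per_condition,
                 noise_sd_uV = noise_sd_uV, effect_scale = effect_scale,
                 latency_shift_ms = latency_shift_ms,
                 amplitude_gain = amplitude_gain,
                 topography_rot_deg = topography_rot_deg,
                 modality_gain = modality_gain,
                 modality_rot_deg = modality_rot_deg,
                 seed = seed),
            class = "sim_config")
}

.effect_for_modality <- function(effect_scale, modality) {
  if (length(effect_scale) == 1 && is.null(names(effect_scale)))
    return(as.numeric(effect_scale))
  stopifnot(modality %in% names(effect_scale))
  as.numeric(effect_scale[[modality]])
}

#' Condition-dependent N100 templates
#'
#' Builds one ERP template per stimulus type.  The base template peaks at
#' 100 ms with amplitude -8 uV at Cz and temporal Gaussian SD 15 ms; its
#' topography is a negative spatial Gaussian kernel centred midway between
#' Cz and FCz plus positive kernels at T7 and T8, evaluated on the montage
#' and normalized to +1 at Cz (so `amplitude_uV` carries the fronto-central
#' sign).  Condition effects (per-frequency latency shift, gain and
#' topography rotation; per-modality gain and contralateral tilt) scale
#' linearly with `effect_scale`; at `effect_scale = 0` all twelve templates
#' are identical.
#'
#' @param effect_scale scalar or named per-modality vector (see
#'   [sim_config()])
#' @param montage montage data.frame; default [default_montage()]
#' @param config optional `sim_config` supplying the perturbation magnitudes
#' @return named list (keys `"<frequency>@<modality>"`) of `erp_template`
#'   objects with fields `latency_ms`, `amplitude_uV`, `width_ms`,
#'   `topography` (named per-channel weights, +1 at Cz).
#' @export
default_templates <- function(effect_scale = 1, montage = default_montage(),
                              config = NULL) {
  if (is.null(config)) config <- sim_config(effect_scale = effect_scale)
  else config$effect_scale <- effect_scale
  stopifnot("Cz" %in% montage$label)
  types <- stimulus_types()
  out <- vector("list", nrow(types))
  names(out) <- .type_key(types$frequency_hz, types$modality)
  freqs <- c(250, 500, 1000, 2000)
  for (i in seq_len(nrow(types))) {
    f <- match(types$frequency_hz[i], freqs)
    m <- types$modality[i]
    es <- .effect_for_modality(config$effect_scale, m)
    lat <- 100 + es * config$latency_shift_ms[f]
    amp <- -8 * (1 + es * config$amplitude_gain[f]) *
      (1 + es * config$modality_gain[[m]])
    rot <- es * (config$topography_rot_deg[f] + config$modality_rot_deg[[m]])
    topo <- .n100_topography(montage, center_az_deg = rot)
    out[[i]] <- structure(list(latency_ms = lat, amplitude_uV = amp,
                               width_ms = 15, topography = topo,
                               frequency_hz = types$frequency_hz[i],
                               modality = m),
                          class = "erp_template")
  }
  out
}

# N100-like scalp map: negative kernel between Cz and FCz (optionally
# rotated in azimuth), positive kernels at T7/T8; normalized to +1 at Cz
.n100_topography <- function(montage, center_az_deg = 0,
                             neg_width_deg = 40, pos_width_deg = 35,
                             pos_rel = 0.6) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  # centre midway between Cz and FCz, tilted by center_az_deg in azimuth
  c0 <- .slerp(.sph(0, 0), .sph(22.5, 0), 0.5)
  if (center_az_deg != 0) {
    th <- acos(c0[3])
    c0 <- .sph(th * 180 / pi, center_az_deg)
  }
  ang <- function(center) {
    d <- pmin(1, pmax(-1, xyz %*% center))
    acos(d) * 180 / pi
  }
  k <- function(center, w) exp(-ang(center)^2 / (2 * w^2))
  # kernel centres are fixed scalp locations (the T7/T8 positions),
  # independent of which channels the montage actually contains
  t7 <- .sph(90, -90)
  t8 <- .sph(90, 90)
  w <- -k(c0, neg_width_deg) + pos_rel * (k(t7, pos_width_deg) +
                                            k(t8, pos_width_deg))
  w <- as.numeric(w)
  names(w) <- montage$label
  w / w[["Cz"]]  # w[Cz] < 0, so division flips sign: +1 at Cz
}

#' Evaluate a template's peak scalp field
#'
#' @param template an `erp_template`
#' @return named numeric vector, microvolts per channel at the peak latency
#'   (i.e. `amplitude_uV * topography`).
#' @export
template_field <- function(template) {
  template$amplitude_uV * template$topography
}

#' Evaluate a template on a time axis (one channel row per montage channel)
#' @noRd
.template_matrix <- function(template, time_ms) {
  bump <- exp(-(time_ms - template$latency_ms)^2 / (2 * template$width_ms^2))
  outer(template_field(template), bump)  # channels x time
}

#' Pink (1/f) noise generator
#'
#' Generates channels x samples Gaussian noise whose power spectral density
#' falls as 1/f above `f_min_hz` and is flat below it (a low-frequency
#' shoulder; without it the variance of a finite 1/f realization is
#' dominated by the few lowest Fourier modes and the sample SD is unstable).
#' The analytic scaling makes the expected per-channel SD equal `sd_uV`.
#'
#' @param n_samples samples per channel (> 1)
#' @param n_channels number of channels
#' @param sd_uV target per-channel standard deviation, microvolts
#' @param seed integer RNG seed (`NULL` to use the current RNG state)
#' @param fs_hz sampling frequency, Hz
#' @param f_min_hz low-frequency shoulder, Hz
#' @return n_channels x n_samples numeric matrix
#' @export
pink_noise <- function(n_samples, n_channels = 1, sd_uV = 1, seed = NULL,
                       fs_hz = 1000, f_min_hz = 1) {
  stopifnot(n_samples > 1, n_channels >= 1, sd_uV >= 0)
  gen <- function() .pink_noise_core(n_samples, n_channels, sd_uV, fs_hz,
                                     f_min_hz)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.pink_gain <- function(n_samples, fs_hz, f_min_hz) {
  k <- seq_len(n_samples) - 1
  f <- pmin(k, n_samples - k) * fs_hz / n_samples  # two-sided frequency
  g <- 1 / sqrt(pmax(f, f_min_hz))
  g[1] <- 0  # zero-mean noise
  g
}

.pink_noise_core <- function(n_samples, n_channels, sd_uV, fs_hz, f_min_hz) {
  if (sd_uV == 0) return(matrix(0, n_channels, n_samples))
  g <- .pink_gain(n_samples, fs_hz, f_min_hz)
  # E[var(x)] = sd_white^2 * mean(g^2); rescale so the expected SD is sd_uV
  scale <- sd_uV / sqrt(mean(g^2))
  w <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n_samples
  t(x) * scale
}

#' Simulate an epoched synthetic ERP dataset
#'
#' Each trial is the template of its stimulus condition evaluated on the
#' epoch time axis (-50..349 ms at 1000 Hz, 400 samples) plus independent
#' per-channel pink noise.  Labels follow the supplied protocol (or a
#' freshly generated default protocol).
#'
#' @param config a [sim_config()]
#' @param protocol optional `stimulus_protocol`; its (frequency, modality)
#'   types must be a subset of the twelve-type space
#' @param montage optional montage data.frame; default
#'   `montage_subset(config$n_channels)`
#' @param require_detectable if `TRUE`, refuse to generate a dataset in which
#'   nothing distinguishes the conditions (all effects zero)
#' @return an `eeg_epochs` object (see [eeg_epochs()]) with attribute
#'   `ground_truth` holding the config and the per-condition templates.
#' @export
simulate_epochs <- function(config = sim_config(), protocol = NULL,
                            montage = NULL, require_detectable = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$noise_sd_uV < 0) stop("noise_sd_uV must be non-negative")
  if (require_detectable && all(config$effect_scale == 0))
    stop("a detectable dataset was requested but effect_scale is 0 ",
         "(all condition templates identical)")
  if (is.null(montage)) montage <- montage_subset(config$n_channels)
  if (is.null(protocol))
    protocol <- generate_protocol(n_per_type = config$trials_per_condition,
                                  seed = config$seed)
  types <- stimulus_types()
  key_all <- .type_key(types$frequency_hz, types$modality)
  key_ev <- .type_key(protocol$frequency_hz, protocol$modality)
  stopifnot(all(key_ev %in% key_all))

  templates <- default_templates(config$effect_scale, montage = montage,
                                 config = config)
  time_ms <- -50:349
  nt <- length(time_ms)
  n_trials <- nrow(protocol)
  nch <- nrow(montage)
  data <- array(0, dim = c(n_trials, nch, nt))
  tmpl_mats <- lapply(templates, .template_matrix, time_ms = time_ms)
  for (i in seq_len(n_trials)) data[i, , ] <- tmpl_mats[[key_ev[i]]]

  if (config$noise_sd_uV > 0) {
    withr::with_seed(config$seed, {
      # epochs behave like cutouts of continuous background activity: one
      # long pink stream per channel, sliced per trial, so each epoch keeps
      # low-frequency power (and a nonzero epoch mean) as real EEG does
      for (ch in seq_len(nch)) {
        stream <- .pink_noise_core(n_trials * nt, 1, config$noise_sd_uV,
                                   config$fs_hz, 1)
        data[, ch, ] <- data[, ch, ] +
          matrix(stream, n_trials, nt, byrow = TRUE)
      }
    })
  }

  ep <- eeg_epochs(data, time_ms = time_ms, channels = montage$label,
                   labels = data.frame(frequency_hz = protocol$frequency_hz,
                                       modality = protocol$modality,
                                       stringsAsFactors = FALSE),
                   montage = montage)
  attr(ep, "ground_truth") <- list(config = config, templates = templates)
  ep
}

#' Simulate a continuous synthetic recording
#'
#' Superimposes condition templates at the protocol onsets on continuous
#' pink noise; mainly used to exercise the epoching and preprocessing chain.
#'
#' @inheritParams simulate_epochs
#' @param pre_ms,post_ms silence margins before the first and after the last
#'   stimulus, ms
#' @return an `eeg_recording` object (see [eeg_recording()]).
#' @export
simulate_recording <- function(config = sim_config(), protocol = NULL,
                               montage = NULL, pre_ms = 500, post_ms = 500) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(montage)) montage <- montage_subset(config$n_channels)
  if (is.null(protocol))
    protocol <- generate_protocol(n_per_type = config$trials_per_condition,
                                  seed = config$seed)
  templates <- default_templates(config$effect_scale, montage = montage,
                                 config = config)
  fs <- config$fs_hz
  onsets <- protocol$onset_ms + pre_ms
  n_samples <- ceiling((max(onsets) + post_ms) * fs / 1000) + 400L
  nch <- nrow(montage)
  data <- if (config$noise_sd_uV > 0)
    pink_noise(n_samples, nch, config$noise_sd_uV, seed = config$seed,
               fs_hz = fs)
  else matrix(0, nch, n_samples)
  key_ev <- .type_key(protocol$frequency_hz, protocol$modality)
  rel_ms <- -50:349
  for (i in seq_along(onsets)) {
    idx0 <- round(onsets[i] * fs / 1000) + 1L
    cols <- idx0 + rel_ms  # template support [-50, 350) around onset
    tm <- .template_matrix(templates[[key_ev[i]]], rel_ms)
    keep <- cols >= 1 & cols <= n_samples
    data[, cols[keep]] <- data[, cols[keep]] + tm[, keep, drop = FALSE]
  }
  ev <- protocol
  ev$onset_ms <- onsets
  eeg_recording(data, fs_hz = fs, channels = montage$label, events = ev,
                montage = montage)
}
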