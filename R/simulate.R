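# Synthetic epoched EEG: component templates + subject gain + AR(1)
# band-limited noise + injectable artifacts.

#' Simulation parameters
#'
#' Bundles everything the epoch generator needs. Defaults emulate the study
#' conditions: 17 subjects, the 61-channel recording montage, 500 Hz
#' sampling, epochs from -100 to 1000 ms around target onset, the default
#' component set, and single-trial noise that is AR(1) at the sample level
#' and low-passed at the 40 Hz acquisition band edge.
#'
#' @param n_subjects Number of subjects.
#' @param channels Channel labels to simulate.
#' @param fs Sampling rate in Hz.
#' @param epoch_window `c(start_ms, end_ms)` relative to target onset;
#'   `start < 0 < end`.
#' @param components List of [component_spec()] objects.
#' @param subject_amp_sd SD of the subject-level multiplicative log-normal
#'   gain (mean-one parameterization); 0 disables subject variability.
#' @param noise_sd Stationary SD of the AR(1) trial noise in microvolts
#'   (before low-pass filtering).
#' @param noise_ar1 Lag-one autocorrelation of the trial noise, in `[0, 1)`.
#' @param lowpass_hz Low-pass edge in Hz applied to the noise (zero-delay
#'   windowed-sinc FIR), mirroring the DC-to-40-Hz acquisition band;
#'   `NA` disables filtering.
#' @param artifact_step_rate Probability per trial of an injected voltage
#'   step artifact on one random channel.
#' @param artifact_step_amp Step amplitude in microvolts.
#' @param artifact_drift_rate Probability per trial of an injected linear
#'   drift artifact spanning the epoch.
#' @param artifact_drift_amp Drift span in microvolts.
#' @param error_rate Probability that a trial is answered incorrectly
#'   (flagged, not removed; exclusion happens at averaging).
#' @param seed Integer master seed.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 17, channels = default_montage(),
                              fs = 500, epoch_window = c(-100, 1000),
                              components = default_components(),
                              subject_amp_sd = 0.2, noise_sd = 10,
                              noise_ar1 = 0.95, lowpass_hz = 40,
                              artifact_step_rate = 0.03,
                              artifact_step_amp = 120,
                              artifact_drift_rate = 0,
                              artifact_drift_amp = 100,
                              error_rate = 0.05, seed = 1L) {
  stopifnot(fs > 0, length(epoch_window) == 2,
            epoch_window[1] < 0, epoch_window[2] > 0,
            subject_amp_sd >= 0, noise_sd >= 0,
            noise_ar1 >= 0, noise_ar1 < 1,
            artifact_step_rate >= 0, artifact_step_rate <= 1,
            artifact_drift_rate >= 0, artifact_drift_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.na(lowpass_hz) && lowpass_hz >= fs / 2) {
    stop("lowpass_hz must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), channels = channels,
                 fs = fs, epoch_window = epoch_window, components = components,
                 subject_amp_sd = subject_amp_sd, noise_sd = noise_sd,
                 noise_ar1 = noise_ar1, lowpass_hz = lowpass_hz,
                 artifact_step_rate = artifact_step_rate,
                 artifact_step_amp = artifact_step_amp,
                 artifact_drift_rate = artifact_drift_rate,
                 artifact_drift_amp = artifact_drift_amp,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Construct an epoched-EEG container
#'
#' @param subject_id Subject identifier.
#' @param fs Sampling rate in Hz.
#' @param time_ms Shared time axis in ms, 0 = target onset; spacing must be
#'   `1000 / fs`.
#' @param channels Ordered channel labels.
#' @param trials List of channel x sample amplitude matrices (microvolts).
#' @param meta data.frame of per-trial metadata (one row per trial), with at
#'   least columns `condition` and `correct`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(subject_id, fs, time_ms, channels, trials, meta) {
  stopifnot(length(trials) == nrow(meta))
  if (length(time_ms) > 1 &&
      max(abs(diff(time_ms) - 1000 / fs)) > 1e-6) {
    stop("time axis spacing must equal 1000/fs ms", call. = FALSE)
  }
  for (tr in trials) {
    if (!is.matrix(tr) || nrow(tr) != length(channels) ||
        ncol(tr) != length(time_ms)) {
      stop("every trial must be a channels x samples matrix on the shared axes",
           call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id, fs = fs, time_ms = time_ms,
                 channels = channels, trials = trials, meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> subject %s: %d trials, %d channels, %d samples (%g..%g ms @ %g Hz)\n",
              x$subject_id, length(x$trials), length(x$channels),
              length(x$time_ms), min(x$time_ms), max(x$time_ms), x$fs))
  invisible(x)
}

# stationary AR(1) noise, optionally FIR low-passed, as an
# (n_samp x n_series) matrix
.ar1_noise <- function(n_samp, n_series, rho, sd_, lowpass_hz, fs) {
  if (sd_ == 0 || n_series == 0) {
    return(matrix(0, n_samp, n_series))
  }
  fir <- NULL
  pad <- 64L # AR(1) burn-in
  if (!is.na(lowpass_hz)) {
    fir <- signal::fir1(64, lowpass_hz / (fs / 2))
    pad <- pad + 64L
  }
  n_tot <- n_samp + 2L * pad
  innov_sd <- sd_ * sqrt(1 - rho^2)
  x <- matrix(stats::rnorm(n_tot * n_series, sd = innov_sd), n_tot, n_series)
  if (rho > 0) {
    x <- stats::filter(x, rho, method = "recursive")
  }
  if (!is.null(fir)) {
    x <- stats::filter(x, fir, method = "convolution", sides = 2)
  }
  x <- as.matrix(x)[pad + seq_len(n_samp), , drop = FALSE]
  storage.mode(x) <- "double"
  x
}

# channel weights for a component topography: direct label match, else the
# weight of the channel's pooled parent, else 0
.channel_weights <- function(topography, channels, map = default_pooling_map()) {
  w <- topography[channels]
  missing <- is.na(w)
  if (any(missing)) {
    parents <- .pool_parent(channels[missing], map)
    w[missing] <- topography[parents]
  }
  w[is.na(w)] <- 0
  unname(w)
}

# noiseless condition template: channels x samples matrix in microvolts
.condition_signal <- function(condition, params, map = default_pooling_map()) {
  time_ms <- .time_axis(params)
  out <- matrix(0, length(params$channels), length(time_ms))
  for (comp in params$components) {
    if (!condition %in% names(comp$amplitude)) {
      stop(sprintf("condition %s has no amplitude entry in component %s",
                   condition, comp$name), call. = FALSE)
    }
    env <- exp(-0.5 * ((time_ms - comp$peak_latency_ms) / comp$width_ms)^2)
    w <- .channel_weights(comp$topography, params$channels, map)
    out <- out + comp$amplitude[[condition]] * tcrossprod(w, env)
  }
  out
}

.time_axis <- function(params) {
  seq(params$epoch_window[1], params$epoch_window[2], by = 1000 / params$fs)
}

#' Simulate one subject's epoched EEG for a session design
#'
#' Each trial is the condition's component template, scaled by the subject's
#' log-normal gain, plus AR(1) band-limited noise; step and drift artifacts
#' are injected at the configured rates, and each trial carries a response
#' correctness flag drawn with `error_rate`. Bit-identical output for equal
#' `(params$seed, subject)`.
#'
#' @param design A `session_design` (or any data.frame with columns
#'   `condition` and `lexicality`).
#' @param params A [simulation_params()] object.
#' @param subject Subject index (used to derive the subject's seed and gain).
#' @param map Pooling map used to resolve topography weights for raw
#'   (unpooled) channel labels.
#' @return An [epoch_set()] whose `meta` carries the design columns plus
#'   `correct` and `artifact` flags.
#' @export
simulate_epochs <- function(design, params, subject = 1L,
                            map = default_pooling_map()) {
  time_ms <- .time_axis(params)
  n_samp <- length(time_ms)
  n_ch <- length(params$channels)
  n_trials <- nrow(design)
  set.seed(derive_seed(params$seed, "subject", subject))

  gain <- if (params$subject_amp_sd > 0) {
    exp(stats::rnorm(1, 0, params$subject_amp_sd) - params$subject_amp_sd^2 / 2)
  } else 1

  conds <- unique(design$condition)
  signal_by_cond <- lapply(conds, .condition_signal, params = params, map = map)
  names(signal_by_cond) <- conds

  noise <- .ar1_noise(n_samp, n_trials * n_ch, params$noise_ar1,
                      params$noise_sd, params$lowpass_hz, params$fs)
  correct <- stats::runif(n_trials) >= params$error_rate
  step_hit <- stats::runif(n_trials) < params$artifact_step_rate
  drift_hit <- stats::runif(n_trials) < params$artifact_drift_rate

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    eps <- t(noise[, (i - 1L) * n_ch + seq_len(n_ch), drop = FALSE])
    x <- gain * signal_by_cond[[design$condition[i]]] + eps
    if (step_hit[i]) {
      ch <- sample.int(n_ch, 1)
      s0 <- sample.int(n_samp - 1L, 1) + 1L
      x[ch, s0:n_samp] <- x[ch, s0:n_samp] +
        sample(c(-1, 1), 1) * params$artifact_step_amp
    }
    if (drift_hit[i]) {
      ch <- sample.int(n_ch, 1)
      x[ch, ] <- x[ch, ] + sample(c(-1, 1), 1) * params$artifact_drift_amp *
        seq(0, 1, length.out = n_samp)
    }
    trials[[i]] <- x
  }
  meta <- as.data.frame(design)
  meta$correct <- correct
  meta$artifact <- step_hit | drift_hit
  epoch_set(subject_id = subject, fs = params$fs, time_ms = time_ms,
            channels = params$channels, trials = trials, meta = meta)
}

#' Simulate a whole study (all subjects)
#'
#' Builds a participant-specific session design for each subject (rotating
#' the Latin square) and simulates their epochs.
#'
#' @param params A [simulation_params()] object.
#' @param design_args List of arguments forwarded to [build_session()]
#'   (participant and seed are supplied per subject).
#' @param map Pooling map for topography resolution.
#' @return List of [epoch_set()] objects, one per subject.
#' @export
simulate_study <- function(params, design_args = list(),
                           map = default_pooling_map()) {
  lapply(seq_len(params$n_subjects), function(s) {
    design <- do.call(build_session,
                      c(design_args,
                        list(participant = s,
                             seed = derive_seed(params$seed, "design", s))))
    simulate_epochs(design, params, subject = s, map = map)
  })
}
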