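# End-to-end orchestration: simulate -> preprocess -> contrast suite ->
# report.

#' Pipeline run configuration
#'
#' Bundles the simulation parameters, analysis configuration and
#' preprocessing switches of one full pipeline run. Defaults follow the
#' study's stated values wherever one exists (50/100 microvolt rejection
#' thresholds, 100 ms pre-target baseline, correct-responses-only averaging,
#' pooling to the 19 standard electrodes).
#'
#' @param sim A [simulation_params()].
#' @param analysis An [analysis_config()].
#' @param design_args Arguments forwarded to [build_session()] per subject.
#' @param drift_method Drift-correction method (default `"none"`: the
#'   synthetic generator produces no DC drift unless asked to).
#' @param step_thresh,range_thresh Artifact-rejection thresholds in
#'   microvolts.
#' @param baseline_window Baseline window in ms.
#' @param correct_only Average correct-response trials only.
#' @param pool Pool electrodes with the default map before analysis.
#' @param roi_time_window Optional ROI detection window in ms (e.g.
#'   `c(0, 1000)` to exclude the baseline from detection).
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = simulation_params(),
                       analysis = analysis_config(),
                       design_args = list(),
                       drift_method = "none",
                       step_thresh = 50, range_thresh = 100,
                       baseline_window = c(-100, 0),
                       correct_only = TRUE, pool = TRUE,
                       roi_time_window = NULL) {
  structure(list(sim = sim, analysis = analysis, design_args = design_args,
                 drift_method = drift_method, step_thresh = step_thresh,
                 range_thresh = range_thresh,
                 baseline_window = baseline_window,
                 correct_only = correct_only, pool = pool,
                 roi_time_window = roi_time_window),
            class = "run_config")
}

# the contrast suite of the priming analysis: test pair, ROI source pair,
# and whether the contrast is a double difference
.contrast_suite <- function() {
  list(
    list(label = "S-U", test = c("S", "U"), roi = c("S", "U")),
    list(label = "T-U", test = c("T", "U"), roi = c("T", "U")),
    list(label = "O-U", test = c("O", "U"), roi = c("O", "U")),
    list(label = "F-U", test = c("F", "U"), roi = c("F", "U")),
    list(label = "T-O", test = c("T", "O"), roi = c("S", "U"),
         restricted = TRUE),
    list(label = "O-F", test = c("O", "F"), roi = c("O", "F")),
    list(label = "(O-F)-(T-S)", double = TRUE, pos = c("O", "F"),
         neg = c("T", "S"))
  )
}

.summarize_contrast <- function(res, ts) {
  roi_tab <- if (!is.null(res$roi)) {
    res$roi$regions[, c("channel", "start_ms", "end_ms", "n_samples")]
  }
  list(label = res$label,
       roi_label = res$roi_label,
       roi = roi_tab,
       observed_tmax = res$observed_tmax,
       critical_t = res$critical_t,
       p_value = res$p_value,
       n_perm = res$n_perm,
       n_sig_points = sum(res$sig_mask),
       null_tmax = res$null_tmax,
       significance = significance_table(res, ts = ts))
}

# run one contrast (simple or double difference) with its ROI source
.run_contrast <- function(erps, spec, cfg, time_window) {
  if (isTRUE(spec$double)) {
    diff <- double_difference(erps, spec$pos, spec$neg)
    roi_diff <- diff
  } else {
    diff <- condition_difference(erps, spec$test)
    roi_diff <- condition_difference(erps, spec$roi)
  }
  roi <- find_rois(pointwise_t(roi_diff), cfg, time_window)
  if (roi_size(roi) == 0) {
    return(list(label = if (isTRUE(spec$double))
      sprintf("(%s-%s)-(%s-%s)", spec$pos[1], spec$pos[2], spec$neg[1],
              spec$neg[2]) else spec$label,
      roi = NULL, observed_tmax = NA_real_, critical_t = NA_real_,
      p_value = NA_real_, n_perm = cfg$n_perm, n_sig_points = 0L,
      note = "running-t detection admitted no region"))
  }
  res <- tmax_permutation(diff, roi, cfg)
  res$roi <- roi
  res$roi_label <- if (isTRUE(spec$double)) res$label else
    paste(spec$roi, collapse = "-")
  .summarize_contrast(res, pointwise_t(diff))
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) per-subject epochs, preprocesses each subject
#' (drift correction, artifact rejection, baseline correction, pooling),
#' averages into subject x condition ERPs, and runs the contrast suite:
#' S-U, T-U, O-U, F-U, the T-O test restricted to the S-U ROI, O-F, and the
#' double difference (O-F)-(T-S). Deterministic given the seeds inside
#' `cfg`.
#'
#' @param cfg A [run_config()].
#' @param epoch_list Optional list of [epoch_set()] objects (one per
#'   subject); simulated from `cfg$sim` when `NULL`.
#' @return An object of class `pipeline_report`: resolved config echo,
#'   per-subject rejection audit, per-condition mean amplitudes in the
#'   400-600 ms window at each channel, and one summary per contrast.
#' @export
run_pipeline <- function(cfg = run_config(), epoch_list = NULL) {
  if (is.null(epoch_list)) {
    epoch_list <- simulate_study(cfg$sim, cfg$design_args)
  }
  audit <- list()
  processed <- vector("list", length(epoch_list))
  for (s in seq_along(epoch_list)) {
    pre <- preprocess_epochs(epoch_list[[s]],
                             drift_method = cfg$drift_method,
                             step_thresh = cfg$step_thresh,
                             range_thresh = cfg$range_thresh,
                             baseline_window = cfg$baseline_window,
                             map = if (cfg$pool) default_pooling_map() else NULL)
    processed[[s]] <- pre$epochs
    audit[[s]] <- data.frame(
      subject = epoch_list[[s]]$subject_id,
      n_trials = length(epoch_list[[s]]$trials),
      n_rejected = nrow(pre$rejections),
      n_step = sum(pre$rejections$criterion %in% c("step", "both")),
      n_range = sum(pre$rejections$criterion %in% c("range", "both"))
    )
  }
  audit <- do.call(rbind, audit)
  erps <- average_erps(processed, conditions = critical_conditions(),
                       correct_only = cfg$correct_only)

  contrasts <- lapply(.contrast_suite(), .run_contrast,
                      erps = erps, cfg = cfg$analysis,
                      time_window = cfg$roi_time_window)
  names(contrasts) <- vapply(contrasts, `[[`, "", "label")

  structure(list(
    config = .echo_config(cfg),
    audit = audit,
    n_trials_averaged = erps$n_trials,
    condition_means = condition_window_means(erps),
    contrasts = contrasts
  ), class = "pipeline_report")
}

#' Mean amplitudes per condition in a time window
#'
#' Grand mean over subjects of each condition's amplitude, averaged over a
#' window (default the 400-600 ms N400 interval), per channel; plus the
#' across-channel centro-parietal summary used for the rank-order checks.
#'
#' @param erps An [erp_set()].
#' @param window `c(start_ms, end_ms)`, inclusive.
#' @param summary_channels Channels entering the pooled summary column
#'   (default the centro-parietal sites Cz, CPz, Pz).
#' @return data.frame: one row per condition, one column per channel, plus
#'   `summary`.
#' @export
condition_window_means <- function(erps, window = c(400, 600),
                                   summary_channels = c("Cz", "CPz", "Pz")) {
  sel <- erps$time_ms >= window[1] & erps$time_ms <= window[2]
  m <- apply(erps$data[, , , sel, drop = FALSE], c(2, 3), mean)
  sc <- intersect(summary_channels, erps$channels)
  out <- as.data.frame(m)
  out$summary <- rowMeans(m[, sc, drop = FALSE])
  cbind(condition = rownames(out), out, row.names = NULL)
}

.echo_config <- function(cfg) {
  sim <- cfg$sim
  list(
    sim = list(n_subjects = sim$n_subjects, n_channels = length(sim$channels),
               fs = sim$fs, epoch_window = sim$epoch_window,
               components = lapply(sim$components, function(c_)
                 list(name = c_$name, peak_latency_ms = c_$peak_latency_ms,
                      width_ms = c_$width_ms,
                      amplitude = as.list(c_$amplitude))),
               subject_amp_sd = sim$subject_amp_sd, noise_sd = sim$noise_sd,
               noise_ar1 = sim$noise_ar1, lowpass_hz = sim$lowpass_hz,
               artifact_step_rate = sim$artifact_step_rate,
               artifact_step_amp = sim$artifact_step_amp,
               error_rate = sim$error_rate, seed = sim$seed),
    analysis = unclass(cfg$analysis),
    drift_method = cfg$drift_method,
    step_thresh = cfg$step_thresh, range_thresh = cfg$range_thresh,
    baseline_window = cfg$baseline_window,
    correct_only = cfg$correct_only, pool = cfg$pool,
    roi_time_window = cfg$roi_time_window
  )
}
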