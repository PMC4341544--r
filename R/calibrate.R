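# Null-simulation calibration of the ROI + maximum-t permutation procedure,
# and power estimation on injected effects.

# simulate one small two-(or more-)condition experiment and run the
# ROI-restricted permutation analysis; returns the per-experiment verdict
.run_null_style_experiment <- function(params, cfg, conditions,
                                       trials_per_condition, roi_pair,
                                       test_pair, time_window,
                                       step_thresh, range_thresh) {
  design <- data.frame(
    block = 1L,
    position = seq_len(length(conditions) * trials_per_condition),
    prime = "prime", target = "target",
    condition = rep(conditions, each = trials_per_condition),
    lexicality = "word",
    stringsAsFactors = FALSE
  )
  epoch_list <- lapply(seq_len(params$n_subjects), function(s) {
    pre <- preprocess_epochs(simulate_epochs(design, params, subject = s),
                             drift_method = "none",
                             step_thresh = step_thresh,
                             range_thresh = range_thresh,
                             map = NULL)
    pre$epochs
  })
  erps <- average_erps(epoch_list, conditions = conditions)
  roi <- find_rois(pointwise_t(condition_difference(erps, roi_pair)),
                   cfg, time_window)
  if (roi_size(roi) == 0) {
    return(list(significant = FALSE, roi_nonempty = FALSE))
  }
  res <- tmax_permutation(condition_difference(erps, test_pair), roi, cfg)
  list(significant = any(res$sig_mask), roi_nonempty = TRUE)
}

.calibration_loop <- function(params, cfg, n_sims, conditions,
                              trials_per_condition, roi_pair, test_pair,
                              time_window, step_thresh, range_thresh) {
  significant <- logical(n_sims)
  roi_nonempty <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    params_i <- params
    params_i$seed <- derive_seed(params$seed, "calibration-sim", i)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, "calibration-perm", i)
    out <- .run_null_style_experiment(params_i, cfg_i, conditions,
                                      trials_per_condition, roi_pair,
                                      test_pair, time_window,
                                      step_thresh, range_thresh)
    significant[i] <- out$significant
    roi_nonempty[i] <- out$roi_nonempty
  }
  ci <- stats::binom.test(sum(significant), n_sims)$conf.int
  n_roi <- sum(roi_nonempty)
  cond_ci <- if (n_roi > 0) {
    as.numeric(stats::binom.test(sum(significant), n_roi)$conf.int)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(rate = mean(significant), ci = as.numeric(ci),
                 n_sims = n_sims, n_significant = sum(significant),
                 roi_nonempty_rate = mean(roi_nonempty),
                 conditional_rate = if (n_roi > 0) sum(significant) / n_roi
                   else NA_real_,
                 conditional_ci = cond_ci,
                 alpha = cfg$alpha, n_perm = cfg$n_perm,
                 roi_pair = roi_pair, test_pair = test_pair),
            class = "fwer_calibration")
}

#' @export
print.fwer_calibration <- function(x, ...) {
  cat(sprintf("<fwer_calibration> %d/%d experiments with any significant point: rate %.3f (95%% CI %.3f-%.3f), nominal alpha %.2f\nROI (%s) non-empty in %.1f%% of experiments; conditional rejection rate %.3f; %d permutations each\n",
              x$n_significant, x$n_sims, x$rate, x$ci[1], x$ci[2], x$alpha,
              paste(x$roi_pair, collapse = "-"), 100 * x$roi_nonempty_rate,
              x$conditional_rate, x$n_perm))
  invisible(x)
}

#' Family-wise error calibration on null simulations
#'
#' Estimates the family-wise error rate of the full analysis chain on data
#' with no condition effects: each replicate simulates a complete experiment
#' (epochs, rejection, baseline, averaging), detects the running-t ROI on
#' `roi_pair`, runs the sign-flip maximum-t permutation of `test_pair`
#' inside it, and counts a family error when any point is declared
#' significant. With the default `test_pair == roi_pair` this calibrates the
#' ROI-selected self-test of the standard priming analysis.
#'
#' @param params A [simulation_params()] whose components carry no
#'   between-condition amplitude differences (e.g.
#'   `components = list()` or `default_components(effect_scale = 0)`);
#'   anything else is a misuse error.
#' @param cfg An [analysis_config()]; `n_perm` is typically reduced (1000)
#'   for calibration.
#' @param n_sims Number of simulated null experiments.
#' @param conditions Condition labels simulated (at least the union of
#'   `roi_pair` and `test_pair`).
#' @param trials_per_condition Trials per condition and subject.
#' @param roi_pair,test_pair Condition pairs for ROI definition and testing.
#' @param time_window Optional ROI detection window in ms.
#' @param step_thresh,range_thresh Artifact-rejection thresholds.
#' @return A `fwer_calibration` object: `rate` (proportion of experiments
#'   with any significant point), exact 95% binomial `ci`, `n_sims`,
#'   `n_significant`, `roi_nonempty_rate`, and `conditional_rate` /
#'   `conditional_ci` (rejection rate among the experiments in which ROI
#'   detection admitted a region, i.e. in which the permutation test was
#'   actually run).
#' @export
calibrate_fwer <- function(params, cfg = analysis_config(n_perm = 1000),
                           n_sims = 500, conditions = c("S", "U"),
                           trials_per_condition = 20,
                           roi_pair = c("S", "U"), test_pair = roi_pair,
                           time_window = NULL,
                           step_thresh = 50, range_thresh = 100) {
  for (comp in params$components) {
    amps <- comp$amplitude[intersect(conditions, names(comp$amplitude))]
    if (length(amps) > 0 && diff(range(amps)) > 0) {
      stop(sprintf("misuse: component %s carries condition effects; FWER calibration requires null data",
                   comp$name), call. = FALSE)
    }
  }
  .calibration_loop(params, cfg, n_sims, conditions, trials_per_condition,
                    roi_pair, test_pair, time_window, step_thresh,
                    range_thresh)
}

#' Rejection rate of the restricted permutation test on injected effects
#'
#' Same simulation harness as [calibrate_fwer()] but without the null
#' restriction: the supplied components may carry condition effects, and the
#' returned rate is the power of the ROI-restricted permutation test against
#' them. At zero injected effect this coincides with the null rejection
#' rate.
#'
#' @inheritParams calibrate_fwer
#' @return A `fwer_calibration` object (the `rate` field is the power).
#' @export
estimate_power <- function(params, cfg = analysis_config(n_perm = 1000),
                           n_sims = 100, conditions = c("S", "U"),
                           trials_per_condition = 20,
                           roi_pair = c("S", "U"), test_pair = roi_pair,
                           time_window = NULL,
                           step_thresh = 50, range_thresh = 100) {
  .calibration_loop(params, cfg, n_sims, conditions, trials_per_condition,
                    roi_pair, test_pair, time_window, step_thresh,
                    range_thresh)
}

#' Reduced-scale simulation parameters for calibration runs
#'
#' The study conditions on a reduced axis: 17 subjects, the 19 pooled
#' channels simulated directly, 250 Hz sampling from -100 to 600 ms, pure
#' AR(1) noise with lag-one correlation 0.90 (the smoothness of
#' 40-Hz-band-limited EEG at this rate), no artifacts, and no condition
#' effects.
#'
#' @param seed Integer master seed.
#' @param components Component list; default none (pure noise).
#' @return A [simulation_params()] object.
#' @export
calibration_params <- function(seed = 1L, components = list()) {
  simulation_params(n_subjects = 17, channels = standard_channels(),
                    fs = 250, epoch_window = c(-100, 600),
                    components = components, subject_amp_sd = 0.2,
                    noise_sd = 10, noise_ar1 = 0.90, lowpass_hz = NA,
                    artifact_step_rate = 0, artifact_drift_rate = 0,
                    error_rate = 0, seed = seed)
}
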