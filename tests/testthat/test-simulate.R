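# Synthetic epoch generator: templates, noise, determinism, recovery.

small_design <- function(conds = c("S", "U"), n_per = 4) {
  data.frame(block = 1L, position = seq_len(length(conds) * n_per),
             prime = "p", target = "t",
             condition = rep(conds, each = n_per), lexicality = "word",
             stringsAsFactors = FALSE)
}

test_that("no components and no noise give exactly zero amplitudes", {
  p <- simulation_params(n_subjects = 1, channels = c("Cz", "Pz"), fs = 250,
                         epoch_window = c(-100, 400), components = list(),
                         noise_sd = 0, subject_amp_sd = 0,
                         artifact_step_rate = 0, error_rate = 0, seed = 1)
  ep <- simulate_epochs(small_design(), p)
  expect_true(all(vapply(ep$trials, function(m) all(m == 0), TRUE)))
})

test_that("a single component evaluates to its closed form at the peak", {
  comp <- component_spec("N400", 450, 60, c(S = -5, U = 0), c(Cz = 1, Pz = 0.5))
  p <- simulation_params(n_subjects = 1, channels = c("Cz", "Pz"), fs = 500,
                         epoch_window = c(-100, 600),
                         components = list(comp), noise_sd = 0,
                         subject_amp_sd = 0, artifact_step_rate = 0,
                         error_rate = 0, seed = 1)
  ep <- simulate_epochs(small_design(), p)
  at_peak <- which(ep$time_ms == 450)
  s_trial <- ep$trials[[which(ep$meta$condition == "S")[1]]]
  u_trial <- ep$trials[[which(ep$meta$condition == "U")[1]]]
  expect_equal(s_trial[1, at_peak], -5)            # Cz, weight 1
  expect_equal(s_trial[2, at_peak], -2.5)          # Pz, weight 0.5
  expect_equal(u_trial[1, at_peak], 0)             # U amplitude 0
  # Gaussian envelope one SD away from the peak
  at_sd <- which(ep$time_ms == 450 + 60)
  expect_equal(s_trial[1, at_sd], -5 * exp(-0.5), tolerance = 1e-12)
})

test_that("subject gain scales the template multiplicatively", {
  comp <- component_spec("N400", 450, 60, c(S = -5, U = 0), c(Cz = 1))
  p <- simulation_params(n_subjects = 2, channels = "Cz", fs = 500,
                         epoch_window = c(-100, 600),
                         components = list(comp), noise_sd = 0,
                         subject_amp_sd = 0.5, artifact_step_rate = 0,
                         error_rate = 0, seed = 4)
  ep1 <- simulate_epochs(small_design(), p, subject = 1)
  at_peak <- which(ep1$time_ms == 450)
  i <- which(ep1$meta$condition == "S")[1]
  gain <- ep1$trials[[i]][1, at_peak] / (-5)
  expect_gt(gain, 0)
  # the whole trial is the template scaled by one gain
  expect_equal(ep1$trials[[i]][1, ],
               gain * -5 * exp(-0.5 * ((ep1$time_ms - 450) / 60)^2),
               tolerance = 1e-9)
})

test_that("equal seeds give bit-identical epoch sets, different seeds differ", {
  p <- simulation_params(n_subjects = 1, channels = c("Cz", "Pz"), fs = 250,
                         epoch_window = c(-100, 400), seed = 7)
  a <- simulate_epochs(small_design(), p, subject = 1)
  b <- simulate_epochs(small_design(), p, subject = 1)
  expect_identical(a, b)
  p2 <- p; p2$seed <- 8L
  c_ <- simulate_epochs(small_design(), p2, subject = 1)
  expect_false(identical(a$trials, c_$trials))
})

test_that("a missing condition amplitude raises a configuration error", {
  comp <- component_spec("N400", 450, 60, c(S = -5), c(Cz = 1))
  p <- simulation_params(n_subjects = 1, channels = "Cz",
                         epoch_window = c(-100, 400),
                         components = list(comp), seed = 1)
  expect_error(simulate_epochs(small_design(), p),
               "no amplitude entry")
})

test_that("grand averages recover the injected amplitude within 3 MC SEs", {
  comp <- component_spec("N400", 300, 50, c(S = -4, U = 0), c(Cz = 1))
  n_trials <- 30
  p <- simulation_params(n_subjects = 8, channels = "Cz", fs = 250,
                         epoch_window = c(-100, 500),
                         components = list(comp), noise_sd = 6,
                         noise_ar1 = 0.9, lowpass_hz = NA,
                         subject_amp_sd = 0, artifact_step_rate = 0,
                         error_rate = 0, seed = 42)
  eps <- lapply(1:8, function(s)
    simulate_epochs(small_design(n_per = n_trials), p, subject = s))
  erps <- average_erps(lapply(eps, baseline_correct),
                       conditions = c("S", "U"))
  at_peak <- which(erps$time_ms == 300)
  d <- erps$data[, "S", 1, at_peak] - erps$data[, "U", 1, at_peak]
  # each subject's S-U at the peak has variance 2*sd^2/n_trials (plus a
  # small baseline-correction term); 3 MC SEs over subjects
  mc_se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (-4)), 3 * mc_se)
})

test_that("with zero artifact rate downstream rejection removes nothing", {
  p <- simulation_params(n_subjects = 1, channels = c("Cz", "Pz"), fs = 250,
                         epoch_window = c(-100, 400), noise_sd = 5,
                         artifact_step_rate = 0, artifact_drift_rate = 0,
                         seed = 2)
  ep <- simulate_epochs(small_design(n_per = 20), p)
  rej <- reject_artifacts(ep)
  expect_equal(nrow(rej$report), 0)
  expect_equal(length(rej$epochs$trials), 40)
})

test_that("injected step artifacts are flagged and large enough to trip rejection", {
  p <- simulation_params(n_subjects = 1, channels = "Cz", fs = 250,
                         epoch_window = c(-100, 400), noise_sd = 0,
                         subject_amp_sd = 0, components = list(),
                         artifact_step_rate = 1, artifact_step_amp = 120,
                         error_rate = 0, seed = 3)
  ep <- simulate_epochs(small_design(n_per = 5), p)
  expect_true(all(ep$meta$artifact))
  rej <- reject_artifacts(ep)
  expect_equal(length(rej$epochs$trials), 0)
  expect_true(all(rej$report$criterion %in% c("step", "both")))
})

test_that("the epoch time axis is spaced at the sampling period", {
  p <- simulation_params(n_subjects = 1, channels = "Cz", fs = 500,
                         epoch_window = c(-100, 1000), components = list(),
                         noise_sd = 0, seed = 1)
  ep <- simulate_epochs(small_design(n_per = 1), p)
  expect_equal(unique(diff(ep$time_ms)), 2)
  expect_equal(length(ep$time_ms), 551)
  expect_true(0 %in% ep$time_ms)
})
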