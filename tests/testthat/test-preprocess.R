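# Preprocessing chain: drift, rejection, baseline, pooling, averaging.

test_that("drift correction: identity, exact line removal, closed-form residual", {
  tt <- seq(-100, 498, by = 2)
  ramp <- matrix(rep(3 + 0.05 * seq_along(tt), 2), nrow = 2, byrow = TRUE)
  ep <- make_epochs(list(ramp))
  expect_identical(correct_drift(ep, "none"), ep)

  out <- correct_drift(ep, "linear_detrend", span = "trial")
  expect_lt(max(abs(out$trials[[1]])), 1e-9)

  # ramp + sinusoid: residual equals the sinusoid minus its own LS line
  sinus <- sin(2 * pi * seq_along(tt) / 60)
  x <- 3 + 0.02 * seq_along(tt) + sinus
  ep2 <- make_epochs(list(rbind(x, x)))
  out2 <- correct_drift(ep2, "linear_detrend", span = "trial")
  fit <- lm(sinus ~ seq_along(tt))
  expect_equal(out2$trials[[1]][1, ], unname(residuals(fit)),
               tolerance = 1e-9)
  expect_error(correct_drift(ep, "spline"), "unknown")
})

test_that("block-span drift correction removes one line across a block's trials", {
  n_samp <- 100
  # two trials forming one continuous ramp across the block
  t1 <- matrix(seq_len(n_samp), 1)
  t2 <- matrix(n_samp + seq_len(n_samp), 1)
  ep <- make_epochs(list(t1, t2), fs = 500, block = c(1L, 1L))
  out <- correct_drift(ep, "linear_detrend", span = "block")
  expect_lt(max(abs(out$trials[[1]])), 1e-8)
  expect_lt(max(abs(out$trials[[2]])), 1e-8)
})

test_that("artifact rejection applies the step and range criteria strictly", {
  n_samp <- 200
  flat <- matrix(5, 2, n_samp)
  stepped <- flat; stepped[1, 101:n_samp] <- 5 + 60   # 60 uV jump
  ramp <- matrix(rep(seq(0, 120, length.out = n_samp), each = 2), 2) # slow
  ep <- make_epochs(list(flat, stepped, ramp),
                    conditions = c("U", "U", "U"))
  rej <- reject_artifacts(ep)
  expect_equal(rej$report$trial, c(2L, 3L))
  expect_equal(rej$report$criterion[rej$report$trial == 2], "step")
  # slow ramp: max step ~0.6 uV, range 120 uV -> range criterion only
  expect_equal(rej$report$criterion[rej$report$trial == 3], "range")
  expect_equal(length(rej$epochs$trials), 1)
  expect_equal(rej$epochs$meta$position, 1L)
})

test_that("rejection boundary sits exactly at the thresholds (strict >)", {
  n_samp <- 50
  step_trial <- function(a) {
    m <- matrix(0, 1, n_samp); m[1, 26:n_samp] <- a; m
  }
  ep_at <- make_epochs(list(step_trial(50)))
  ep_over <- make_epochs(list(step_trial(50 + 1e-9)))
  expect_equal(nrow(reject_artifacts(ep_at)$report), 0)
  expect_equal(nrow(reject_artifacts(ep_over)$report), 1)
  ramp_trial <- function(a) matrix(seq(0, a, length.out = n_samp), 1)
  expect_equal(nrow(reject_artifacts(make_epochs(list(ramp_trial(100))))$report), 0)
  expect_equal(nrow(reject_artifacts(make_epochs(list(ramp_trial(100.001))))$report), 1)
})

test_that("rejection is monotone in its thresholds", {
  set.seed(11)
  trials <- lapply(1:30, function(i) matrix(rnorm(2 * 80, sd = 30), 2, 80))
  ep <- make_epochs(trials)
  n_rej <- function(st, rt) nrow(reject_artifacts(ep, st, rt)$report)
  base <- n_rej(50, 100)
  expect_gte(base, n_rej(60, 100))
  expect_gte(base, n_rej(50, 120))
  expect_gte(n_rej(40, 100), base)
})

test_that("baseline correction zeroes the pre-stimulus window mean", {
  n_samp <- 300
  const <- matrix(10, 2, n_samp)
  ep <- make_epochs(list(const))
  out <- baseline_correct(ep)
  expect_true(all(out$trials[[1]] == 0))

  set.seed(2)
  ep2 <- make_epochs(list(matrix(rnorm(2 * n_samp), 2, n_samp)))
  out2 <- baseline_correct(ep2)
  sel <- out2$time_ms >= -100 & out2$time_ms < 0
  expect_lt(max(abs(rowMeans(out2$trials[[1]][, sel]))), 1e-9)

  # arithmetic example: baseline mean 3.2, peak 1.0 -> corrected peak -2.2
  tr <- matrix(0, 1, n_samp)
  tr[1, ep$time_ms < 0] <- 3.2
  tr[1, ep$time_ms >= 0] <- 1.0
  out3 <- baseline_correct(make_epochs(list(tr)))
  expect_equal(out3$trials[[1]][1, which.max(ep$time_ms)], -2.2)

  expect_error(baseline_correct(ep, window = c(-500, -400)),
               "window")
})

test_that("the sample at stimulus onset is excluded from the baseline", {
  n_samp <- 100
  tr <- matrix(0, 1, n_samp)
  ep0 <- make_epochs(list(tr))
  tr[1, ep0$time_ms == 0] <- 50 # huge value exactly at onset
  out <- baseline_correct(make_epochs(list(tr)))
  sel <- out$time_ms < 0
  expect_true(all(out$trials[[1]][1, sel] == 0))
})

test_that("pooling the default map reduces 61 channels to 19 three-channel means", {
  map <- default_pooling_map()
  expect_length(map, 19)
  expect_true(all(lengths(map) == 3))
  montage <- default_montage()
  expect_length(montage, 61)
  set.seed(3)
  trials <- lapply(1:2, function(i) matrix(rnorm(61 * 40), 61, 40))
  ep <- make_epochs(trials, channels = montage)
  out <- pool_electrodes(ep)
  expect_equal(out$channels, names(map))
  expect_length(out$channels, 19)
  # each pooled channel is the arithmetic mean of its three members
  for (k in c(1, 10, 19)) {
    idx <- match(map[[k]], montage)
    expect_equal(out$trials[[1]][k, ],
                 colMeans(trials[[1]][idx, ]), tolerance = 1e-12)
  }
})

test_that("pooling identical channels is the identity; 1,2,3 pools to 2", {
  m <- rbind(rep(1, 10), rep(2, 10), rep(3, 10))
  ep <- make_epochs(list(m), channels = c("a", "b", "c"))
  out <- pool_electrodes(ep, map = list(X = c("a", "b", "c")))
  expect_equal(out$trials[[1]][1, ], rep(2, 10))
  same <- make_epochs(list(rbind(m[1, ], m[1, ], m[1, ])),
                      channels = c("a", "b", "c"))
  out2 <- pool_electrodes(same, map = list(X = c("a", "b", "c")))
  expect_equal(out2$trials[[1]][1, ], m[1, ])
  expect_error(pool_electrodes(ep, map = list(X = c("a", "b", "zz"))),
               "montage mismatch")
})

test_that("pooling and baselining commute (both linear)", {
  set.seed(8)
  trials <- lapply(1:3, function(i) matrix(rnorm(6 * 120), 6, 120))
  ep <- make_epochs(trials, channels = letters[1:6])
  map <- list(X = c("a", "b", "c"), Y = c("d", "e", "f"))
  a <- baseline_correct(pool_electrodes(ep, map))
  b <- pool_electrodes(baseline_correct(ep), map)
  expect_equal(a$trials, b$trials, tolerance = 1e-12)
})

test_that("averaging respects conditions, correctness flags and counts", {
  n_samp <- 20
  one <- matrix(1, 1, n_samp); minus <- matrix(-1, 1, n_samp)
  ep <- make_epochs(list(one, minus, one, one),
                    conditions = c("S", "S", "U", "U"),
                    correct = c(TRUE, TRUE, TRUE, FALSE))
  erps <- average_erps(list(ep), conditions = c("S", "U"))
  expect_equal(erps$data[1, "S", 1, ], rep(0, n_samp))   # (+1 -1)/2
  expect_equal(erps$data[1, "U", 1, ], rep(1, n_samp))   # only correct trial
  expect_equal(unname(erps$n_trials[1, ]), c(2L, 1L))
  all_in <- average_erps(list(ep), conditions = c("S", "U"),
                         correct_only = FALSE)
  expect_equal(unname(all_in$n_trials[1, ]), c(2L, 2L))
  ep_bad <- make_epochs(list(one), conditions = "S")
  expect_error(average_erps(list(ep_bad), conditions = c("S", "U")),
               "subject s1, condition U")
})

test_that("preprocessing is deterministic and ordered", {
  p <- simulation_params(n_subjects = 1, channels = default_montage(),
                         fs = 250, epoch_window = c(-100, 400), seed = 5)
  d <- data.frame(block = 1L, position = 1:10, prime = "p", target = "t",
                  condition = "U", lexicality = "word")
  ep <- simulate_epochs(d, p)
  a <- preprocess_epochs(ep)
  b <- preprocess_epochs(ep)
  expect_identical(a, b)
  expect_length(a$epochs$channels, 19)
})
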