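# Pointwise t, running-t ROI detection, sign-flip max-t permutation.

test_that("pointwise t matches the hand-computed one-sample t", {
  d <- array(0, c(5, 1, 3))
  d[, 1, 2] <- 1:5  # mean 3, sd 1.5811 -> t = 4.2426
  ts <- pointwise_t(make_diff(d))
  expect_equal(ts$t[1, 1], 0)               # zero variance, zero mean
  expect_equal(ts$t[1, 2], 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(round(ts$t[1, 2], 4), 4.2426)
  expect_equal(ts$df, 4L)
  d17 <- array(rnorm(17 * 2 * 4), c(17, 2, 4))
  expect_equal(pointwise_t(make_diff(d17))$df, 16L)
  expect_error(pointwise_t(make_diff(array(1, c(1, 1, 1)))), "2 subjects")
})

test_that("zero-variance nonzero-mean points hit the documented cap", {
  d <- array(2, c(4, 1, 2))
  d[, 1, 2] <- -3
  ts <- pointwise_t(make_diff(d))
  expect_equal(ts$t[1, 1], 1e6)
  expect_equal(ts$t[1, 2], -1e6)
})

test_that("pointwise t agrees with the loop oracle on random arrays", {
  set.seed(31)
  d <- array(rnorm(7 * 3 * 10), c(7, 3, 10))
  ts <- pointwise_t(make_diff(d))
  for (ch in 1:3) {
    for (s in c(1, 5, 10)) {
      expect_equal(ts$t[ch, s], oracle_t(d[, ch, s]), tolerance = 1e-10)
    }
  }
})

test_that("translation invariance: adding a constant to both conditions leaves t unchanged", {
  set.seed(12)
  base <- array(rnorm(6 * 2 * 8), c(6, 2, 8))
  delta <- array(rnorm(6 * 2 * 8, mean = 0.5), c(6, 2, 8))
  # same condition difference, with and without a common offset
  a <- array(0, c(6, 2, 2, 8)); a[, 1, , ] <- base + 9; a[, 2, , ] <- base + 9 + delta
  erps <- make_erps(a, conditions = c("A", "B"))
  b <- array(0, c(6, 2, 2, 8)); b[, 1, , ] <- base; b[, 2, , ] <- base + delta
  erps2 <- make_erps(b, conditions = c("A", "B"))
  t1 <- pointwise_t(condition_difference(erps, c("A", "B")))
  t2 <- pointwise_t(condition_difference(erps2, c("A", "B")))
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
})

test_that("ROI detection applies the 50 ms duration rule exactly at 500 Hz", {
  n_samp <- 200
  t_mat <- matrix(0, 1, n_samp)
  t_crit <- qt(0.975, df = 16)
  t_mat[1, 11:34] <- t_crit + 1   # 24 samples = 48 ms -> excluded
  t_mat[1, 101:130] <- -(t_crit + 1) # 30 samples = 60 ms -> admitted
  ts <- structure(list(t = t_mat, df = 16L, n = 17L, channels = "Cz",
                       time_ms = seq(0, by = 2, length.out = n_samp),
                       fs = 500, label = "S-U"), class = "t_series")
  roi <- find_rois(ts)
  expect_equal(nrow(roi$regions), 1)
  expect_equal(roi$regions$n_samples, 30)
  expect_equal(roi$regions$start_ms, 200)
  # 25 samples = exactly 50 ms -> admitted ("at least")
  t_mat2 <- matrix(0, 1, n_samp); t_mat2[1, 11:35] <- t_crit + 1
  ts$t <- t_mat2
  expect_equal(find_rois(ts)$regions$n_samples, 25)
  # sub-threshold everywhere -> empty
  ts$t <- matrix(0, 1, n_samp)
  expect_equal(nrow(find_rois(ts)$regions), 0)
})

test_that("ROI detection matches a brute-force run scan on random t fields", {
  set.seed(77)
  for (rep_ in 1:5) {
    tm <- matrix(rnorm(3 * 80, sd = 2), 3, 80)
    ts <- structure(list(t = tm, df = 9L, n = 10L,
                         channels = paste0("c", 1:3),
                         time_ms = seq(0, by = 4, length.out = 80),
                         fs = 250, label = "x"), class = "t_series")
    cfg <- analysis_config(min_duration_ms = 20) # 5 samples at 250 Hz
    roi <- find_rois(ts, cfg)
    thresh <- qt(0.975, 9)
    expected <- 0L
    for (ch in 1:3) {
      expected <- expected +
        length(oracle_runs(tm[ch, ], thresh, 5))
    }
    expect_equal(nrow(roi$regions), expected)
    if (nrow(roi$regions) > 0) {
      # every admitted point is supra-threshold
      for (i in seq_len(nrow(roi$regions))) {
        r <- roi$regions[i, ]
        expect_true(all(abs(tm[r$chan_index,
                               r$start_index:r$end_index]) > thresh))
      }
    }
  }
})

test_that("all-zero differences give t_max 0 and p-value 1", {
  d <- array(0, c(6, 2, 10))
  diff <- make_diff(d)
  roi <- make_roi(1L, 1L, 10L, diff$channels, diff$time_ms)
  res <- tmax_permutation(diff, roi, analysis_config(n_perm = 200))
  expect_equal(res$observed_tmax, 0)
  expect_equal(res$p_value, 1)
  expect_false(any(res$sig_mask))
})

test_that("permutation p agrees with exhaustive enumeration for n = 8", {
  set.seed(19)
  d <- array(rnorm(8 * 2 * 5, mean = 0.7), c(8, 2, 5))
  diff <- make_diff(d)
  roi <- make_roi(c(1L, 2L), c(1L, 1L), c(5L, 5L), diff$channels,
                  diff$time_ms)
  res <- tmax_permutation(diff, roi, analysis_config(n_perm = 4000, seed = 3))
  p_ex <- oracle_exhaustive_p(d)
  se <- sqrt(p_ex * (1 - p_ex) / 4000)
  expect_lt(abs(res$p_value - p_ex), 3 * se + 1 / 4001)
  expect_equal(res$observed_tmax, oracle_tmax(d), tolerance = 1e-10)
})

test_that("sign-flip symmetry: negating all subjects leaves the result invariant", {
  set.seed(23)
  d <- array(rnorm(9 * 2 * 6, mean = 0.4), c(9, 2, 6))
  diff_pos <- make_diff(d)
  diff_neg <- make_diff(-d)
  roi <- make_roi(1L, 1L, 6L, diff_pos$channels, diff_pos$time_ms)
  cfg <- analysis_config(n_perm = 2000, seed = 5)
  a <- tmax_permutation(diff_pos, roi, cfg)
  b <- tmax_permutation(diff_neg, roi, cfg)
  expect_equal(a$observed_tmax, b$observed_tmax, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$critical_t, b$critical_t, tolerance = 1e-12)
})

test_that("the critical value is the nearest-rank 95th percentile", {
  set.seed(4)
  d <- array(rnorm(6 * 1 * 4), c(6, 1, 4))
  diff <- make_diff(d)
  roi <- make_roi(1L, 1L, 4L, diff$channels, diff$time_ms)
  res <- tmax_permutation(diff, roi, analysis_config(n_perm = 100, seed = 9))
  expect_equal(res$critical_t, sort(res$null_tmax)[95])
  expect_length(res$null_tmax, 100)
})

test_that("permutation results are reproducible and flagged inside the ROI only", {
  set.seed(41)
  d <- array(rnorm(10 * 3 * 12, mean = 1.2), c(10, 3, 12))
  diff <- make_diff(d)
  roi <- make_roi(2L, 3L, 10L, diff$channels, diff$time_ms)
  cfg <- analysis_config(n_perm = 1000, seed = 2)
  a <- tmax_permutation(diff, roi, cfg)
  b <- tmax_permutation(diff, roi, cfg)
  expect_identical(a, b)
  outside <- a$sig_mask
  outside[2, 3:10] <- FALSE
  expect_false(any(outside))
  expect_error(tmax_permutation(diff, make_roi(integer(0), integer(0),
                                               integer(0), diff$channels,
                                               diff$time_ms), cfg),
               "nothing to test")
})

test_that("double differences compute the configured arithmetic", {
  a <- array(0, c(3, 4, 1, 2))
  a[, 1, , ] <- 1; a[, 2, , ] <- 0; a[, 3, , ] <- 3; a[, 4, , ] <- 1
  erps <- make_erps(a, conditions = c("O", "F", "T", "S"))
  dd <- double_difference(erps, c("O", "F"), c("T", "S"))
  expect_equal(unique(as.vector(dd$data)), -1) # (1-0) - (3-1)
  expect_equal(dd$label, "(O-F)-(T-S)")
  same <- make_erps(a[, c(1, 1, 3, 3), , , drop = FALSE],
                    conditions = c("O", "F", "T", "S"))
  dd0 <- double_difference(same, c("O", "F"), c("T", "S"))
  expect_true(all(dd0$data == 0))
  expect_error(double_difference(erps, c("O", "F"), c("O", "S")),
               "distinct")
})

test_that("restricted contrasts: identical conditions are null, injected effects detected", {
  set.seed(55)
  n_sub <- 12; n_ch <- 3; n_samp <- 100
  noise <- function() array(rnorm(n_sub * n_ch * n_samp, sd = 0.8),
                            c(n_sub, 1, n_ch, n_samp))
  # S-U effect defines the ROI window (samples 40..70); T == O exactly
  erp <- array(0, c(n_sub, 4, n_ch, n_samp))
  eff <- array(0, c(n_sub, 1, n_ch, n_samp)); eff[, , 1:2, 40:70] <- 2.5
  shared <- noise()
  erp[, 1, , ] <- noise() + eff          # S
  erp[, 2, , ] <- noise()                # U
  erp[, 3, , ] <- shared                 # T
  erp[, 4, , ] <- shared                 # O (identical to T)
  erps <- make_erps(erp, conditions = c("S", "U", "T", "O"))
  cfg <- analysis_config(n_perm = 1000, seed = 7)
  null_res <- restricted_contrast(erps, c("T", "O"), c("S", "U"), cfg)
  expect_equal(null_res$p_value, 1) # all differences exactly zero
  # now a genuine T-O effect inside the S-U window
  erp[, 3, , ] <- shared + eff * 0.8
  erps2 <- make_erps(erp, conditions = c("S", "U", "T", "O"))
  eff_res <- restricted_contrast(erps2, c("T", "O"), c("S", "U"), cfg)
  expect_lt(eff_res$p_value, 0.05)
  expect_gt(sum(eff_res$sig_mask), 0)
  # self-test mode reproduces the descriptive S-U analysis
  self_res <- restricted_contrast(erps2, c("S", "U"), c("S", "U"), cfg)
  expect_equal(self_res$roi_label, "S-U")
  expect_lt(self_res$p_value, 0.05)
})

test_that("an empty ROI source is reported, not silently passed", {
  set.seed(66)
  erp <- array(rnorm(8 * 2 * 2 * 50, sd = 1), c(8, 2, 2, 50))
  erps <- make_erps(erp, conditions = c("S", "U"))
  # with pure noise at these sizes a 50 ms run is effectively impossible
  expect_error(restricted_contrast(erps, c("S", "U"), c("S", "U"),
                                   analysis_config(n_perm = 100, seed = 1)),
               "admitted no region")
})
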