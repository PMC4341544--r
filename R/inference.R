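# Resampling inference: pointwise paired t statistics, running-t ROI
# detection with a minimum-duration rule, and the sign-flip maximum-t
# permutation test.

# cap used in place of an infinite t when the paired differences have zero
# variance but nonzero mean
T_CAP <- 1e6

#' Analysis configuration
#'
#' @param alpha Two-tailed pointwise significance level of the running-t ROI
#'   detection (and nominal level of the permutation test).
#' @param min_duration_ms Minimum duration a supra-threshold run must last to
#'   be admitted as a region of interest; the 50 ms default is 25 samples at
#'   500 Hz.
#' @param n_perm Number of sign-flip permutation draws.
#' @param quantile Quantile of the null maximum-t distribution used as the
#'   critical value; must equal `1 - alpha`.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, min_duration_ms = 50,
                            n_perm = 10000, quantile = 1 - alpha,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_duration_ms >= 0, n_perm >= 1)
  if (abs(quantile - (1 - alpha)) > 1e-12) {
    stop("quantile must equal 1 - alpha", call. = FALSE)
  }
  structure(list(alpha = alpha, min_duration_ms = min_duration_ms,
                 n_perm = as.integer(n_perm), quantile = quantile,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Paired condition differences per subject
#'
#' Builds the subject x channel x sample array of paired differences
#' `pair[1] - pair[2]` from an ERP set; this array is the unit the sign-flip
#' permutation operates on (one +/-1 per subject flips the subject's whole
#' array, preserving its spatio-temporal correlation).
#'
#' @param erps An [erp_set()].
#' @param pair Character vector of two condition labels, e.g. `c("S", "U")`.
#' @return An object of class `difference_array` with fields `data`
#'   (`subject x channel x sample`), `label`, `channels`, `time_ms`, `fs`.
#' @export
condition_difference <- function(erps, pair) {
  stopifnot(inherits(erps, "erp_set"), length(pair) == 2)
  miss <- setdiff(pair, erps$conditions)
  if (length(miss) > 0) {
    stop(sprintf("condition(s) %s not present in the ERP set",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d <- erps$data[, pair[1], , , drop = FALSE] -
    erps$data[, pair[2], , , drop = FALSE]
  dim(d) <- dim(erps$data)[c(1, 3, 4)]
  structure(list(data = d, label = paste0(pair[1], "-", pair[2]),
                 channels = erps$channels, time_ms = erps$time_ms,
                 fs = erps$fs),
            class = "difference_array")
}

#' Double difference of two condition pairs
#'
#' Per subject, `(pos[1] - pos[2]) - (neg[1] - neg[2])`; used for the
#' form-versus-meaning contrast `(O - F) - (T - S)`.
#'
#' @param erps An [erp_set()].
#' @param pos,neg Character vectors of two condition labels each; the four
#'   conditions must be distinct.
#' @return A `difference_array` labelled `"(a-b)-(c-d)"`.
#' @export
double_difference <- function(erps, pos, neg) {
  conds <- c(pos, neg)
  if (length(conds) != 4 || anyDuplicated(conds)) {
    stop("pos and neg must name four distinct conditions", call. = FALSE)
  }
  dp <- condition_difference(erps, pos)
  dn <- condition_difference(erps, neg)
  dp$data <- dp$data - dn$data
  dp$label <- sprintf("(%s)-(%s)", dp$label, dn$label)
  dp
}

# core paired-t computation on an n x P matrix of differences (P points)
.t_stat <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0 # numerical guard
  se <- sqrt(v / n)
  t <- m / se
  zero_var <- se == 0
  if (any(zero_var)) {
    t[zero_var] <- ifelse(m[zero_var] == 0, 0, sign(m[zero_var]) * T_CAP)
  }
  # the cap also bounds near-degenerate variances arising from rounding
  pmin(pmax(t, -T_CAP), T_CAP)
}

#' Pointwise paired t statistics
#'
#' One-sample t of the subject differences against zero at every
#' (channel, sample): `t = mean(d) / (sd(d) / sqrt(n))` with the n-1 sample
#' SD. Zero-variance convention: `t = 0` when the mean is also zero,
#' otherwise `sign(mean) * 1e6`.
#'
#' @param diff A [condition_difference()] result.
#' @return An object of class `t_series`: `t` (channel x sample matrix),
#'   `df = n - 1`, `n`, plus the axes.
#' @export
pointwise_t <- function(diff) {
  n <- dim(diff$data)[1]
  if (n < 2) {
    stop("pointwise t requires at least 2 subjects", call. = FALSE)
  }
  n_ch <- dim(diff$data)[2]
  n_samp <- dim(diff$data)[3]
  d <- diff$data
  dim(d) <- c(n, n_ch * n_samp)
  t <- matrix(.t_stat(d), n_ch, n_samp)
  structure(list(t = t, df = n - 1L, n = n, channels = diff$channels,
                 time_ms = diff$time_ms, fs = diff$fs, label = diff$label),
            class = "t_series")
}

#' Detect regions of interest by the running-t duration rule
#'
#' Marks every (channel, sample) whose `|t|` exceeds the two-tailed Student
#' critical value `t(df, 1 - alpha/2)` and returns, per channel, the maximal
#' supra-threshold runs lasting at least `min_duration_ms`. Run duration is
#' the number of samples times the sample period, so a 25-sample run at
#' 500 Hz counts as exactly 50 ms and is admitted.
#'
#' @param ts A [pointwise_t()] result.
#' @param cfg An [analysis_config()].
#' @param time_window Optional `c(start_ms, end_ms)` restricting detection
#'   (inclusive); `NULL` scans the whole axis.
#' @return An object of class `roi_set`: data.frame `regions` with columns
#'   `channel`, `start_ms`, `end_ms`, `n_samples`, plus the sample-index
#'   ranges used internally.
#' @export
find_rois <- function(ts, cfg = analysis_config(), time_window = NULL) {
  stopifnot(inherits(ts, "t_series"))
  t_crit <- stats::qt(1 - cfg$alpha / 2, df = ts$df)
  sample_ms <- 1000 / ts$fs
  min_len <- ceiling(cfg$min_duration_ms / sample_ms - 1e-9)
  in_win <- if (is.null(time_window)) {
    rep(TRUE, length(ts$time_ms))
  } else {
    ts$time_ms >= time_window[1] & ts$time_ms <= time_window[2]
  }
  regions <- list()
  for (ch in seq_along(ts$channels)) {
    supra <- abs(ts$t[ch, ]) > t_crit & in_win
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (any(keep)) {
      regions[[length(regions) + 1L]] <- data.frame(
        channel = ts$channels[ch],
        start_ms = ts$time_ms[starts[keep]],
        end_ms = ts$time_ms[ends[keep]],
        n_samples = r$lengths[keep],
        chan_index = ch,
        start_index = starts[keep],
        end_index = ends[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  regions <- if (length(regions) > 0) {
    do.call(rbind, regions)
  } else {
    data.frame(channel = character(0), start_ms = numeric(0),
               end_ms = numeric(0), n_samples = integer(0),
               chan_index = integer(0), start_index = integer(0),
               end_index = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(regions = regions, t_crit = t_crit,
                 channels = ts$channels, time_ms = ts$time_ms, fs = ts$fs),
            class = "roi_set")
}

#' Number of (channel, sample) points inside an ROI set
#' @param roi A [find_rois()] result.
#' @return Integer count.
#' @export
roi_size <- function(roi) {
  if (nrow(roi$regions) == 0) return(0L)
  sum(roi$regions$n_samples)
}

# (channel index, sample index) matrix of all roi points
.roi_points <- function(roi) {
  if (nrow(roi$regions) == 0) {
    return(cbind(integer(0), integer(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(roi$regions)), function(i) {
    r <- roi$regions[i, ]
    cbind(r$chan_index, r$start_index:r$end_index)
  }))
}

#' Sign-flip maximum-t permutation test within an ROI
#'
#' Simulates the paired null hypothesis (x and -x equally likely) by
#' flipping each subject's whole difference array with an independent +/-1,
#' recomputing the pointwise t at every ROI point, and recording the maximum
#' absolute t over all ROI channels and time points per draw. The critical
#' value is the nearest-rank `quantile` (95th percentile by default) of this
#' null maximum-t distribution; the p-value uses the add-one convention
#' `(1 + #{null >= observed}) / (1 + n_perm)`. Points whose observed `|t|`
#' exceeds the critical value are flagged significant.
#'
#' @param diff A [condition_difference()] (or [double_difference()]) result.
#' @param roi A [find_rois()] result; must be non-empty.
#' @param cfg An [analysis_config()].
#' @return An object of class `perm_result`: `observed_tmax`, `null_tmax`
#'   (length `n_perm`), `critical_t`, `p_value`, `sig_mask`
#'   (channel x sample logical, `TRUE` only inside the ROI), `n_perm`,
#'   `seed`, `label`.
#' @export
tmax_permutation <- function(diff, roi, cfg = analysis_config()) {
  pts <- .roi_points(roi)
  if (nrow(pts) == 0) {
    stop("nothing to test: the ROI set is empty", call. = FALSE)
  }
  n <- dim(diff$data)[1]
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  # n x P matrix of differences at the roi points
  d <- matrix(diff$data[cbind(rep(seq_len(n), nrow(pts)),
                              rep(pts[, 1], each = n),
                              rep(pts[, 2], each = n))],
              nrow = n)
  t_obs <- .t_stat(d)
  observed_tmax <- max(abs(t_obs))

  set.seed(derive_seed(cfg$seed, "perm", diff$label))
  B <- cfg$n_perm
  signs <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
  # per-point sum of squares is invariant under sign flips
  ss <- colSums(d^2)
  M <- signs %*% d / n                       # B x P flipped means
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1) # flipped variances
  V[V < 0] <- 0
  Tm <- abs(M) / sqrt(V / n)
  if (any(!is.finite(Tm))) {
    zero <- !is.finite(Tm)
    Tm[zero] <- ifelse(abs(M)[zero] == 0, 0, T_CAP)
  }
  Tm <- pmin(Tm, T_CAP)
  null_tmax <- apply(Tm, 1, max)

  critical_t <- sort(null_tmax)[ceiling(cfg$quantile * B)]
  p_value <- (1 + sum(null_tmax >= observed_tmax)) / (1 + B)
  sig_mask <- matrix(FALSE, length(diff$channels), length(diff$time_ms))
  sig <- abs(t_obs) > critical_t
  sig_mask[pts[sig, , drop = FALSE]] <- TRUE
  structure(list(observed_tmax = observed_tmax, null_tmax = null_tmax,
                 critical_t = critical_t, p_value = p_value,
                 sig_mask = sig_mask, n_perm = B, seed = cfg$seed,
                 label = diff$label, channels = diff$channels,
                 time_ms = diff$time_ms),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s: observed t_max = %.3f, critical = %.3f (%d perms), p = %.4g, %d significant point(s)\n",
              x$label, x$observed_tmax, x$critical_t, x$n_perm, x$p_value,
              sum(x$sig_mask)))
  invisible(x)
}

#' ROI-restricted permutation contrast
#'
#' Defines the region of interest from the running-t analysis of one
#' condition pair (by default the standard semantic-priming contrast) and
#' runs the sign-flip maximum-t permutation test of another pair inside that
#' ROI. With `test_pair == roi_pair` this reproduces the descriptive
#' ROI-selected self-test of the standard priming effect; with distinct
#' pairs it is the confirmatory restricted test (e.g. T-O inside the S-U
#' ROI).
#'
#' @param erps An [erp_set()].
#' @param test_pair Conditions whose difference is tested.
#' @param roi_pair Conditions whose running-t defines the ROI.
#' @param cfg An [analysis_config()].
#' @param time_window Optional detection window forwarded to [find_rois()].
#' @return A `perm_result` with an added `roi` field.
#' @export
restricted_contrast <- function(erps, test_pair, roi_pair = c("S", "U"),
                                cfg = analysis_config(), time_window = NULL) {
  roi <- find_rois(pointwise_t(condition_difference(erps, roi_pair)),
                   cfg, time_window)
  if (roi_size(roi) == 0) {
    stop(sprintf("nothing to test: the running-t analysis of %s-%s admitted no region",
                 roi_pair[1], roi_pair[2]), call. = FALSE)
  }
  res <- tmax_permutation(condition_difference(erps, test_pair), roi, cfg)
  res$roi <- roi
  res$roi_label <- paste0(roi_pair[1], "-", roi_pair[2])
  res
}
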