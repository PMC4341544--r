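# Preprocessing chain: drift correction -> artifact rejection -> baseline
# correction -> electrode pooling -> per-condition averaging.

#' Correct slow DC drift
#'
#' `method = "none"` is the identity. `method = "linear_detrend"` removes,
#' per channel, the least-squares line fitted over each block's concatenated
#' trials (`span = "block"`) or over each trial separately
#' (`span = "trial"`). This is a documented linear-detrend drift corrector,
#' not the original cited DC-correction algorithm, which is not publicly
#' specified.
#'
#' @param epochs An [epoch_set()].
#' @param method `"none"` or `"linear_detrend"`.
#' @param span `"block"` (default; requires a `block` column in the
#'   metadata) or `"trial"`.
#' @return The drift-corrected `epoch_set`.
#' @export
correct_drift <- function(epochs, method = c("none", "linear_detrend"),
                          span = c("block", "trial")) {
  if (!is.character(method) || !method[1] %in% c("none", "linear_detrend")) {
    stop(sprintf("unknown drift-correction method '%s'", method[1]),
         call. = FALSE)
  }
  method <- match.arg(method)
  span <- match.arg(span)
  if (method == "none") {
    return(epochs)
  }
  detrend_mat <- function(m, tt) {
    # least-squares line per row against tt
    X <- cbind(1, tt)
    beta <- solve(crossprod(X), crossprod(X, t(m)))
    m - t(X %*% beta)
  }
  if (span == "trial") {
    epochs$trials <- lapply(epochs$trials, detrend_mat, tt = epochs$time_ms)
  } else {
    if (is.null(epochs$meta$block)) {
      stop("span = 'block' requires a 'block' column in the trial metadata",
           call. = FALSE)
    }
    n_samp <- length(epochs$time_ms)
    for (b in unique(epochs$meta$block)) {
      idx <- which(epochs$meta$block == b)
      wide <- do.call(cbind, epochs$trials[idx]) # channels x (trials*samples)
      tt <- seq_len(ncol(wide))                  # concatenated sample index
      wide <- detrend_mat(wide, tt)
      for (j in seq_along(idx)) {
        epochs$trials[[idx[j]]] <-
          wide[, (j - 1L) * n_samp + seq_len(n_samp), drop = FALSE]
      }
    }
  }
  epochs
}

#' Reject trials with step or range artifacts
#'
#' A trial is removed iff, on any channel, the absolute voltage step between
#' consecutive samples exceeds `step_thresh` (strictly), or the absolute
#' difference between the trial's maximum and minimum amplitude exceeds
#' `range_thresh` (strictly). Defaults are the 50 / 100 microvolt criteria.
#'
#' @param epochs An [epoch_set()].
#' @param step_thresh Maximum allowed per-sample voltage step (microvolts).
#' @param range_thresh Maximum allowed within-trial peak-to-peak amplitude
#'   (microvolts).
#' @param channels Channels entering the criteria (default: all).
#' @return List with elements `epochs` (retained trials) and `report`
#'   (data.frame: `trial`, `criterion` in `"step"`, `"range"`, `"both"`).
#' @export
reject_artifacts <- function(epochs, step_thresh = 50, range_thresh = 100,
                             channels = NULL) {
  stopifnot(step_thresh > 0, range_thresh > 0)
  keep_ch <- if (is.null(channels)) {
    seq_along(epochs$channels)
  } else {
    match(channels, epochs$channels)
  }
  if (anyNA(keep_ch)) stop("unknown channel in 'channels'", call. = FALSE)
  row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, "first"))]
  step_viol <- vapply(epochs$trials, function(m) {
    mm <- m[keep_ch, , drop = FALSE]
    max(abs(mm[, -1, drop = FALSE] - mm[, -ncol(mm), drop = FALSE]))
  }, numeric(1)) > step_thresh
  range_viol <- vapply(epochs$trials, function(m) {
    mm <- m[keep_ch, , drop = FALSE]
    max(row_max(mm) + row_max(-mm))
  }, numeric(1)) > range_thresh
  bad <- step_viol | range_viol
  report <- data.frame(
    trial = which(bad),
    criterion = ifelse(step_viol[bad] & range_viol[bad], "both",
                       ifelse(step_viol[bad], "step", "range")),
    stringsAsFactors = FALSE
  )
  epochs$trials <- epochs$trials[!bad]
  epochs$meta <- epochs$meta[!bad, , drop = FALSE]
  rownames(epochs$meta) <- NULL
  list(epochs = epochs, report = report)
}

#' Baseline-correct epochs to the pre-stimulus interval
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window. The window is half-open `[start, end)`: with the default
#' `c(-100, 0)` the 100 ms preceding target onset is used and the sample at
#' onset belongs to the response.
#'
#' @param epochs An [epoch_set()].
#' @param window `c(start_ms, end_ms)`.
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  sel <- epochs$time_ms >= window[1] & epochs$time_ms < window[2]
  if (!any(sel)) {
    stop("baseline window contains no samples of the epoch time axis",
         call. = FALSE)
  }
  if (window[1] < min(epochs$time_ms) - 1e-9) {
    stop("baseline window starts before the epoch", call. = FALSE)
  }
  epochs$trials <- lapply(epochs$trials, function(m) {
    m - rowMeans(m[, sel, drop = FALSE])
  })
  epochs
}

#' Pool electrodes to a reduced montage
#'
#' Each pooled channel is the sample-wise unweighted mean of its member
#' channels; the output carries exactly the pooled labels in map order.
#'
#' @param epochs An [epoch_set()].
#' @param map A pooling map (named list: pooled label -> member labels), e.g.
#'   [default_pooling_map()].
#' @return The pooled `epoch_set`.
#' @export
pool_electrodes <- function(epochs, map = default_pooling_map()) {
  raw <- unlist(map, use.names = FALSE)
  missing <- setdiff(raw, epochs$channels)
  if (length(missing) > 0) {
    stop(sprintf("montage mismatch: recording channel(s) %s not present",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx <- lapply(map, match, table = epochs$channels)
  epochs$trials <- lapply(epochs$trials, function(m) {
    out <- do.call(rbind, lapply(idx, function(i) {
      colMeans(m[i, , drop = FALSE])
    }))
    rownames(out) <- NULL
    out
  })
  epochs$channels <- names(map)
  epochs
}

#' Construct a subject x condition x channel x sample ERP container
#'
#' @param data 4-d array `[subject, condition, channel, sample]` of mean
#'   amplitudes in microvolts, with dimnames on subjects, conditions and
#'   channels.
#' @param time_ms Shared time axis.
#' @param fs Sampling rate in Hz.
#' @param n_trials subject x condition matrix of trial counts entering each
#'   average.
#' @return An object of class `erp_set`.
#' @export
erp_set <- function(data, time_ms, fs, n_trials) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] == length(time_ms),
            all(dim(n_trials) == dim(data)[1:2]))
  structure(list(data = data, time_ms = time_ms, fs = fs,
                 subjects = dimnames(data)[[1]],
                 conditions = dimnames(data)[[2]],
                 channels = dimnames(data)[[3]],
                 n_trials = n_trials),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp_set> %d subjects x %d conditions x %d channels x %d samples (%g..%g ms)\n",
              length(x$subjects), length(x$conditions), length(x$channels),
              length(x$time_ms), min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Average epochs into subject x condition ERPs
#'
#' Averages each subject's retained trials separately per condition (and
#' channel and sample). With `correct_only = TRUE` only trials flagged as
#' correct responses enter the averages.
#'
#' @param epoch_list List of [epoch_set()] objects, one per subject, on a
#'   shared time axis and channel order.
#' @param conditions Conditions to average (default: the five critical
#'   conditions).
#' @param correct_only Drop incorrect-response trials before averaging.
#' @return An [erp_set()].
#' @export
average_erps <- function(epoch_list, conditions = critical_conditions(),
                         correct_only = TRUE) {
  stopifnot(length(epoch_list) >= 1)
  ref <- epoch_list[[1]]
  n_sub <- length(epoch_list)
  n_ch <- length(ref$channels)
  n_samp <- length(ref$time_ms)
  data <- array(NA_real_, c(n_sub, length(conditions), n_ch, n_samp),
                dimnames = list(vapply(epoch_list, function(e)
                  as.character(e$subject_id), ""), conditions, ref$channels,
                  NULL))
  n_trials <- matrix(0L, n_sub, length(conditions),
                     dimnames = dimnames(data)[1:2])
  for (s in seq_len(n_sub)) {
    ep <- epoch_list[[s]]
    keep <- if (correct_only) ep$meta$correct else rep(TRUE, nrow(ep$meta))
    for (j in seq_along(conditions)) {
      idx <- which(keep & ep$meta$condition == conditions[j])
      if (length(idx) == 0) {
        stop(sprintf("no retained trials for subject %s, condition %s",
                     ep$subject_id, conditions[j]), call. = FALSE)
      }
      acc <- ep$trials[[idx[1]]]
      if (length(idx) > 1) {
        for (i in idx[-1]) acc <- acc + ep$trials[[i]]
      }
      data[s, j, , ] <- acc / length(idx)
      n_trials[s, j] <- length(idx)
    }
  }
  erp_set(data, ref$time_ms, ref$fs, n_trials)
}

#' Run the full preprocessing chain on one subject
#'
#' Fixed order: drift correction, artifact rejection, baseline correction,
#' electrode pooling. Returns the processed epochs plus the rejection report.
#'
#' @param epochs An [epoch_set()].
#' @param drift_method Passed to [correct_drift()].
#' @param step_thresh,range_thresh Passed to [reject_artifacts()].
#' @param baseline_window Passed to [baseline_correct()].
#' @param map Pooling map, or `NULL` to skip pooling.
#' @return List with `epochs` and `rejections`.
#' @export
preprocess_epochs <- function(epochs, drift_method = "none",
                              step_thresh = 50, range_thresh = 100,
                              baseline_window = c(-100, 0),
                              map = default_pooling_map()) {
  epochs <- correct_drift(epochs, drift_method)
  rej <- reject_artifacts(epochs, step_thresh, range_thresh)
  epochs <- baseline_correct(rej$epochs, baseline_window)
  if (!is.null(map)) {
    epochs <- pool_electrodes(epochs, map)
  }
  list(epochs = epochs, rejections = rej$report)
}
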