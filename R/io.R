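# Epoch interchange format: a JSON sidecar (axes + trial metadata) plus a
# delimited amplitude payload. Amplitudes are serialized as C99 hexadecimal
# floating-point literals ("%a"), which round-trip doubles exactly while
# remaining plain text.

.sidecar_required <- c("format", "version", "subject_id", "fs", "time_ms",
                       "channels", "trials")

#' Write / read an epoch set
#'
#' `write_epochs` stores an [epoch_set()] as a directory holding
#' `sidecar.json` (format version, subject, sampling rate, time axis,
#' channel labels, per-trial metadata) and `amplitudes.tsv` (one row per
#' trial x channel; amplitude columns are hexadecimal float literals, so the
#' round trip is lossless). `read_epochs` validates the sidecar and
#' reconstructs the epoch set exactly.
#'
#' @param epochs An [epoch_set()].
#' @param dir Directory to create/fill (one epoch set per directory).
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` returns the
#'   [epoch_set()].
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list(
    format = "erpperm-epochs", version = 1L,
    subject_id = epochs$subject_id, fs = epochs$fs,
    time_ms = epochs$time_ms, channels = epochs$channels,
    trials = epochs$meta
  )
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "sidecar.json"))
  n_ch <- length(epochs$channels)
  amp <- do.call(rbind, epochs$trials) # (trials*channels) x samples
  payload <- data.table::as.data.table(
    matrix(sprintf("%a", amp), nrow = nrow(amp))
  )
  data.table::setnames(payload, paste0("s", seq_len(ncol(amp))))
  payload <- cbind(
    data.table::data.table(
      trial = rep(seq_along(epochs$trials), each = n_ch),
      channel = rep(epochs$channels, length(epochs$trials))
    ),
    payload
  )
  data.table::fwrite(payload, file.path(dir, "amplitudes.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  sidecar_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sidecar_path)) {
    stop("no sidecar.json in ", dir, call. = FALSE)
  }
  sidecar <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  missing <- setdiff(.sidecar_required, names(sidecar))
  if (length(missing) > 0) {
    stop(sprintf("malformed sidecar: missing field(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (sidecar$format != "erpperm-epochs" || sidecar$version != 1L) {
    stop(sprintf("unsupported epoch format '%s' version %s",
                 sidecar$format, sidecar$version), call. = FALSE)
  }
  payload <- data.table::fread(file.path(dir, "amplitudes.tsv"), sep = "\t",
                               colClasses = "character", showProgress = FALSE)
  n_ch <- length(sidecar$channels)
  n_samp <- length(sidecar$time_ms)
  amp_cols <- paste0("s", seq_len(n_samp))
  amp <- vapply(amp_cols, function(cl) as.numeric(payload[[cl]]),
                numeric(nrow(payload)))
  amp <- matrix(amp, nrow = nrow(payload))
  trial_ids <- as.integer(payload$trial)
  trials <- lapply(split(seq_len(nrow(payload)), trial_ids), function(rows) {
    m <- amp[rows, , drop = FALSE] # rows are this trial's channels, in order
    dimnames(m) <- NULL
    m
  })
  names(trials) <- NULL
  meta <- as.data.frame(sidecar$trials, stringsAsFactors = FALSE)
  epoch_set(subject_id = sidecar$subject_id, fs = sidecar$fs,
            time_ms = sidecar$time_ms, channels = sidecar$channels,
            trials = trials, meta = meta)
}

#' Serialize an analysis report as JSON
#'
#' Writes the [run_pipeline()] report (resolved configuration, design
#' summary, preprocessing audit, condition means, contrast results and
#' significance tables) as pretty-printed JSON. Equal seeds produce
#' byte-identical files.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output file.
#' @param save_null Keep the full null maximum-t distributions (large);
#'   dropped by default.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, save_null = FALSE) {
  out <- unclass(report)
  if (!save_null) {
    out$contrasts <- lapply(out$contrasts, function(ct) {
      ct$null_tmax <- NULL
      ct
    })
  }
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "columns",
                              na = "null"),
             path)
  invisible(path)
}

#' Significance table of a permutation result
#'
#' Long-format table of every ROI point: channel, time, observed t, and
#' whether the point exceeds the permutation critical value; the layout
#' behind a significance raster display.
#'
#' @param res A `perm_result` (with `roi`, as returned by
#'   [restricted_contrast()]), or a `perm_result` plus explicit `roi`.
#' @param roi Optional [find_rois()] result if `res` lacks one.
#' @param ts Optional [pointwise_t()] result supplying observed t values;
#'   recomputed positions are taken from the ROI.
#' @return data.frame with columns `channel`, `time_ms`, `t`, `significant`.
#' @export
significance_table <- function(res, roi = res$roi, ts = NULL) {
  stopifnot(inherits(res, "perm_result"), !is.null(roi))
  pts <- .roi_points(roi)
  data.frame(
    channel = res$channels[pts[, 1]],
    time_ms = res$time_ms[pts[, 2]],
    t = if (is.null(ts)) NA_real_ else ts$t[pts],
    significant = res$sig_mask[pts],
    stringsAsFactors = FALSE
  )
}
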