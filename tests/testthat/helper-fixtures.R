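# Small in-code fixtures shared across tests.

# epoch set built directly from a list of channel x sample matrices
make_epochs <- function(trials, fs = 500, t0 = -100,
                        conditions = rep("U", length(trials)),
                        correct = rep(TRUE, length(trials)),
                        channels = NULL, block = 1L) {
  n_samp <- ncol(trials[[1]])
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(trials[[1]])))
  }
  time_ms <- t0 + (seq_len(n_samp) - 1) * 1000 / fs
  epoch_set(subject_id = "s1", fs = fs, time_ms = time_ms,
            channels = channels, trials = trials,
            meta = data.frame(block = block,
                              position = seq_along(trials),
                              condition = conditions, lexicality = "word",
                              correct = correct,
                              stringsAsFactors = FALSE))
}

# difference_array wrapper around a subject x channel x sample array
make_diff <- function(d, fs = 500, t0 = 0, label = "A-B") {
  structure(list(data = d, label = label,
                 channels = paste0("ch", seq_len(dim(d)[2])),
                 time_ms = t0 + (seq_len(dim(d)[3]) - 1) * 1000 / fs,
                 fs = fs),
            class = "difference_array")
}

# roi_set covering explicit sample ranges on given channels
make_roi <- function(chan_index, start_index, end_index, channels, time_ms,
                     fs = 500) {
  structure(list(
    regions = data.frame(channel = channels[chan_index],
                         start_ms = time_ms[start_index],
                         end_ms = time_ms[end_index],
                         n_samples = end_index - start_index + 1L,
                         chan_index = chan_index,
                         start_index = start_index, end_index = end_index,
                         stringsAsFactors = FALSE),
    t_crit = 0, channels = channels, time_ms = time_ms, fs = fs),
    class = "roi_set")
}

# erp_set from a subject x condition x channel x sample array
make_erps <- function(data, fs = 500, t0 = 0, conditions = NULL) {
  if (is.null(conditions)) conditions <- dimnames(data)[[2]]
  dimnames(data) <- list(paste0("s", seq_len(dim(data)[1])), conditions,
                         paste0("ch", seq_len(dim(data)[3])), NULL)
  erp_set(data, time_ms = t0 + (seq_len(dim(data)[4]) - 1) * 1000 / fs,
          fs = fs,
          n_trials = matrix(1L, dim(data)[1], dim(data)[2],
                            dimnames = dimnames(data)[1:2]))
}
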