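# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# one-sample t by the textbook formula
oracle_t <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) {
    return(if (mean(x) == 0) 0 else sign(mean(x)) * 1e6)
  }
  mean(x) / (s / sqrt(n))
}

# max |t| over all points of an n x chan x sample difference array
oracle_tmax <- function(d) {
  mx <- 0
  for (ch in seq_len(dim(d)[2])) {
    for (s in seq_len(dim(d)[3])) {
      mx <- max(mx, abs(oracle_t(d[, ch, s])))
    }
  }
  mx
}

# exhaustive sign-flip null: t_max for every one of the 2^n sign patterns
oracle_exhaustive_null <- function(d) {
  n <- dim(d)[1]
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  apply(signs, 1, function(sg) {
    flipped <- d
    for (i in seq_len(n)) flipped[i, , ] <- sg[i] * d[i, , ]
    oracle_tmax(flipped)
  })
}

# exhaustive p-value: proportion of sign patterns at least as extreme
oracle_exhaustive_p <- function(d) {
  null <- oracle_exhaustive_null(d)
  mean(null >= oracle_tmax(d) - 1e-10)
}

# brute-force supra-threshold run scan for one channel's t vector
oracle_runs <- function(tvec, thresh, min_len) {
  runs <- list()
  i <- 1
  while (i <= length(tvec)) {
    if (abs(tvec[i]) > thresh) {
      j <- i
      while (j < length(tvec) && abs(tvec[j + 1]) > thresh) j <- j + 1
      if (j - i + 1 >= min_len) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}
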