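# Deterministic seed derivation: every random stage draws from a child seed
# computed from the master seed plus a label, so stages are independent and
# reproducible regardless of evaluation order.

#' Derive a child seed from a master seed and a label
#'
#' All randomness in the package flows from one integer master seed through
#' this splitting scheme: each random stage (design shuffling, each subject's
#' noise, each permutation analysis, each calibration replicate) uses
#' `derive_seed(master, "stage-label")` so that stages draw from independent,
#' reproducible streams.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the stage (concatenated).
#' @return An integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @examples
#' derive_seed(1, "subject", 3)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  label <- paste(vapply(list(...), paste, "", collapse = "."), collapse = ".")
  m <- 2147483647 # 2^31 - 1, Mersenne prime; arithmetic stays exact in doubles
  h <- abs(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
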