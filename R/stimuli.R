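# Prime-target conditions, trial timing, and the synthetic stimulus lexicon.
#
# Condition codes used throughout:
#   U  unrelated prime
#   S  semantically related, morphologically unrelated prime
#   T  morphologically related, semantically transparent (compositional) prime
#   O  morphologically related, semantically opaque prime
#   F  form-related (orthographically similar) prime
#   FILLER  filler pair (word or pseudoword target)

#' Critical prime conditions
#'
#' The five within-subject priming conditions applied to every critical
#' target: unrelated (U), semantically related (S), morphologically related
#' and semantically transparent (T), morphologically related and semantically
#' opaque (O), and form-related (F).
#'
#' @return Character vector `c("U","S","T","O","F")`.
#' @export
critical_conditions <- function() c("U", "S", "T", "O", "F")

#' All condition labels including fillers
#' @return Character vector of the five critical conditions plus `"FILLER"`.
#' @export
all_conditions <- function() c(critical_conditions(), "FILLER")

#' Trial timeline of the priming procedure
#'
#' Durations in ms of the events of one trial: fixation cross, prime, blank
#' interval, target, delay until the response prompt, and inter-trial
#' interval. The stimulus onset asynchrony (SOA) between prime onset and
#' target onset is derived as `prime_ms + blank_ms`; defaults give the
#' 200 + 100 = 300 ms SOA of the overt-priming procedure.
#'
#' @param fixation_ms,prime_ms,blank_ms,target_ms,prompt_delay_ms,iti_ms
#'   Event durations in ms; all must be positive.
#' @return An object of class `trial_timeline`: a named list of the durations
#'   plus the derived `soa_ms`.
#' @examples
#' trial_timeline()$soa_ms  # 300
#' @export
trial_timeline <- function(fixation_ms = 1000, prime_ms = 200, blank_ms = 100,
                           target_ms = 500, prompt_delay_ms = 1000,
                           iti_ms = 2000) {
  durations <- c(fixation_ms = fixation_ms, prime_ms = prime_ms,
                 blank_ms = blank_ms, target_ms = target_ms,
                 prompt_delay_ms = prompt_delay_ms, iti_ms = iti_ms)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all trial timeline durations must be positive", call. = FALSE)
  }
  out <- as.list(durations)
  out$soa_ms <- prime_ms + blank_ms
  structure(out, class = "trial_timeline")
}

#' Position-specific letter overlap between prime and target
#'
#' Percentage of target letter positions at which the prime carries the same
#' letter, case-insensitive. Strings of unequal length are compared up to the
#' shorter one; the denominator is the target length by default (so a prime
#' that contains the target as a proper prefix scores below 100).
#'
#' @param prime,target Character vectors (recycled to common length); no
#'   element may be empty.
#' @param denominator `"target"` (default) divides by the target length,
#'   `"longer"` by the longer of the two strings.
#' @return Numeric vector of overlap percentages in `[0, 100]`.
#' @examples
#' letter_overlap("zielen", "ziehen") # 83.3: five of six positions match
#' letter_overlap("tarnen", "ziehen") # 33.3: only "-en" matches
#' @export
letter_overlap <- function(prime, target, denominator = c("target", "longer")) {
  denominator <- match.arg(denominator)
  if (length(prime) == 0 || length(target) == 0 ||
      any(is.na(prime)) || any(is.na(target)) ||
      any(!nzchar(prime)) || any(!nzchar(target))) {
    stop("prime and target must be non-empty strings", call. = FALSE)
  }
  n <- max(length(prime), length(target))
  prime <- rep_len(tolower(prime), n)
  target <- rep_len(tolower(target), n)
  vapply(seq_len(n), function(i) {
    p <- strsplit(prime[i], "")[[1]]
    t <- strsplit(target[i], "")[[1]]
    k <- min(length(p), length(t))
    matches <- sum(p[seq_len(k)] == t[seq_len(k)])
    den <- switch(denominator,
                  target = length(t),
                  longer = max(length(p), length(t)))
    100 * matches / den
  }, numeric(1))
}

# -- synthetic lexicon ---------------------------------------------------------

.consonants <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s",
                 "t", "w", "z")
.vowels <- c("a", "e", "i", "o", "u")
.prefixes <- c("zu", "er", "be", "ver", "an", "ab", "ent", "um")

# one pronounceable stem, e.g. "tarn", "ziel"; variable length (3-6 letters)
# keeps the position-specific overlap of unrelated pairs low, as misaligned
# "-en" suffixes then rarely coincide
.random_stem <- function(len = NULL) {
  if (is.null(len)) len <- sample(3:6, 1, prob = c(0.2, 0.4, 0.25, 0.15))
  body <- c(sample(.consonants, 1), sample(.vowels, 1))
  while (length(body) < len) {
    body <- c(body, if (length(body) %% 3 == 2)
      sample(.consonants, 1) else sample(c(.consonants, .vowels), 1))
  }
  paste(body, collapse = "")
}

.unique_stems <- function(n, len = NULL) {
  stems <- character(0)
  while (length(stems) < n) {
    stems <- unique(c(stems, replicate(2 * n, .random_stem(len))))
  }
  stems[seq_len(n)]
}

# alter the first rime consonant of a stem -> form-related neighbour
.form_neighbour <- function(stem) {
  letters_ <- strsplit(stem, "")[[1]]
  pos <- 3L
  repl <- sample(setdiff(.consonants, letters_[pos]), 1)
  letters_[pos] <- repl
  paste(letters_, collapse = "")
}

#' Generate a synthetic stimulus set with the study's structural relations
#'
#' Builds pseudo-German infinitives (stem + "-en") and, for each target, one
#' prime per critical condition: T and O primes are prefixed forms that
#' contain the whole target (morphological relatives), F primes share the
#' onset and differ in one rime letter (orthographic neighbours), S and U
#' primes are independent simple forms. Only the structural/overlap
#' properties of the original material are emulated, not its lexicon.
#'
#' @param n_targets Number of critical targets.
#' @param seed Integer seed.
#' @return A data.frame with columns `target` and `prime_U`, `prime_S`,
#'   `prime_T`, `prime_O`, `prime_F`.
#' @export
make_stimulus_set <- function(n_targets = 36, seed = 1L) {
  set.seed(derive_seed(seed, "stimuli"))
  # 4-letter target stems (6-letter infinitives); S and U primes are
  # independent variable-length stems
  targets <- paste0(.unique_stems(n_targets, len = 4), "en")
  s_primes <- paste0(.unique_stems(n_targets), "en")
  u_primes <- paste0(.unique_stems(n_targets), "en")
  pref <- vapply(seq_len(n_targets), function(i) {
    sample(.prefixes, 2, replace = FALSE)
  }, character(2))
  data.frame(
    target = targets,
    prime_U = u_primes,
    prime_S = s_primes,
    prime_T = paste0(pref[1, ], targets),
    prime_O = paste0(pref[2, ], targets),
    prime_F = paste0(vapply(sub("en$", "", targets), .form_neighbour, ""),
                     "en"),
    stringsAsFactors = FALSE
  )
}

#' Mean letter overlap between primes and targets, by condition
#'
#' Validation summary of a session or stimulus set: per condition, the mean
#' and SD of the position-specific letter overlap between prime and target.
#'
#' @param trials A data.frame with columns `prime`, `target`, `condition`
#'   (e.g. a [build_session()] result).
#' @return A data.frame with columns `condition`, `n`, `mean_overlap`,
#'   `sd_overlap`.
#' @export
overlap_summary <- function(trials) {
  stopifnot(all(c("prime", "target", "condition") %in% names(trials)))
  ov <- letter_overlap(trials$prime, trials$target)
  out <- do.call(rbind, lapply(split(ov, trials$condition), function(x) {
    data.frame(n = length(x), mean_overlap = mean(x), sd_overlap = sd(x))
  }))
  data.frame(condition = rownames(out), out, row.names = NULL)
}
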