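# Session design: Latin-square rotation of primes over blocks, filler
# allocation, and within-block randomization under a lexicality-run limit.

#' Default filler composition
#'
#' Filler counts by category for a whole session: 180 pairs with pseudoword
#' targets that are form-related to the critical targets, 180 with word
#' targets, and 180 with unrelated pseudoword targets (540 fillers in all,
#' reducing the critical pairs to 25% of the material). Each count must be
#' divisible by the number of blocks.
#'
#' @return Named integer vector with elements `word`, `pseudoword`,
#'   `pseudoword_form`.
#' @export
default_filler_spec <- function() {
  c(word = 180L, pseudoword = 180L, pseudoword_form = 180L)
}

.make_fillers <- function(filler_spec, targets, seed) {
  set.seed(derive_seed(seed, "fillers"))
  total <- sum(filler_spec)
  if (total == 0) {
    return(data.frame(prime = character(0), target = character(0),
                      condition = character(0), lexicality = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  prime_stems <- .unique_stems(total)
  primes <- paste0(prime_stems, "en")
  # 40% of filler primes are complex (prefixed) verbs, as in the material
  complex <- seq_len(total) %in% sample.int(total, round(0.4 * total))
  primes[complex] <- paste0(sample(.prefixes, sum(complex), replace = TRUE),
                            primes[complex])
  target_stems <- .unique_stems(total)
  cats <- rep(names(filler_spec), filler_spec)
  tg <- paste0(target_stems, "en")
  form_idx <- which(cats == "pseudoword_form")
  if (length(form_idx) > 0) {
    # pseudoword neighbours of the critical targets (e.g. *stehmen ~ stehlen)
    base <- rep_len(sub("en$", "", targets), length(form_idx))
    tg[form_idx] <- paste0(vapply(base, .form_neighbour, ""), "en")
  }
  data.frame(prime = primes, target = tg, condition = "FILLER",
             lexicality = ifelse(cats == "word", "word", "pseudoword"),
             category = cats, stringsAsFactors = FALSE)
}

# longest run of equal values
.max_run <- function(x) if (length(x) == 0) 0L else max(rle(x)$lengths)

#' Build a randomized experimental session
#'
#' Rotates the primes of each critical target over the session's blocks
#' according to a Latin-square scheme: each target appears once per condition,
#' in every second block (so a target never occurs in adjacent blocks), with
#' the condition order cyclically shifted by target and participant. Fillers
#' are divided evenly over blocks, and trial order within each block is
#' randomized under the constraint that no more than `max_lex_run` adjacent
#' targets share lexicality (word vs pseudoword).
#'
#' With the default parameters (36 targets, 5 conditions, 10 blocks, 540
#' fillers) a session has 720 trials, 72 per block, of which 180 are critical
#' pairs (25%).
#'
#' @param n_targets Number of critical targets (must be even so targets split
#'   over the two block parities).
#' @param conditions Critical condition labels; one block parity hosts
#'   `length(conditions)` occurrences of each of its targets, so `n_blocks`
#'   must equal `2 * length(conditions)`.
#' @param n_blocks Number of blocks.
#' @param filler_spec Named counts of filler pairs (see
#'   [default_filler_spec()]); each count divisible by `n_blocks`.
#' @param participant Participant index; shifts the Latin-square rotation so
#'   different participants see different prime orders.
#' @param seed Integer seed (drives stimuli, filler allocation and shuffling).
#' @param stimuli Optional stimulus set from [make_stimulus_set()]; generated
#'   when `NULL`.
#' @param max_lex_run Maximum allowed run of adjacent equal-lexicality
#'   targets.
#' @param max_retries Rejection-sampling retries per block before failing.
#' @return An object of class `session_design`: a data.frame with columns
#'   `block`, `position`, `prime`, `target`, `condition`, `lexicality`, and
#'   attributes `participant`, `n_blocks`, `seed`.
#' @examples
#' d <- build_session(seed = 7)
#' nrow(d)            # 720
#' table(d$block)[1]  # 72
#' @export
build_session <- function(n_targets = 36, conditions = critical_conditions(),
                          n_blocks = 10, filler_spec = default_filler_spec(),
                          participant = 1L, seed = 1L, stimuli = NULL,
                          max_lex_run = 4L, max_retries = 1000L) {
  n_cond <- length(conditions)
  if (n_targets %% 2 != 0) {
    stop("n_targets must be even (targets split over two block parities)",
         call. = FALSE)
  }
  if (n_blocks != 2 * n_cond) {
    stop("n_blocks must equal 2 * length(conditions) for the ",
         "every-second-block rotation", call. = FALSE)
  }
  if (length(filler_spec) > 0 && any(filler_spec %% n_blocks != 0)) {
    stop("each filler count must be divisible by n_blocks", call. = FALSE)
  }
  if (is.null(stimuli)) stimuli <- make_stimulus_set(n_targets, seed = seed)
  stopifnot(nrow(stimuli) == n_targets)

  # target i of parity p occupies blocks p, p+2, ..., p+2*(n_cond-1);
  # its condition at occurrence k is rotated cyclically by target and
  # participant, giving the all-ones target x condition incidence
  parity <- rep(1:2, each = n_targets / 2)
  critical <- do.call(rbind, lapply(seq_len(n_targets), function(i) {
    ks <- seq_len(n_cond)
    cond <- conditions[((i + ks + as.integer(participant) - 2L) %% n_cond) + 1L]
    data.frame(
      block = parity[i] + 2L * (ks - 1L),
      prime = unlist(stimuli[i, paste0("prime_", cond)], use.names = FALSE),
      target = stimuli$target[i],
      condition = cond,
      lexicality = "word",
      stringsAsFactors = FALSE
    )
  }))

  fillers <- .make_fillers(filler_spec, stimuli$target, seed)
  set.seed(derive_seed(seed, "blocks", participant))
  if (nrow(fillers) > 0) {
    # deal each filler category evenly over blocks, in shuffled order, so
    # blocks stay balanced in lexicality and filler composition
    fillers <- fillers[sample.int(nrow(fillers)), ]
    fillers$block <- NA_integer_
    for (cat in unique(fillers$category)) {
      idx <- which(fillers$category == cat)
      fillers$block[idx] <- rep(seq_len(n_blocks), each = length(idx) / n_blocks)
    }
  }

  blocks <- lapply(seq_len(n_blocks), function(b) {
    tr <- rbind(critical[critical$block == b,
                         c("block", "prime", "target", "condition", "lexicality")],
                if (nrow(fillers) > 0)
                  fillers[fillers$block == b,
                          c("block", "prime", "target", "condition", "lexicality")])
    # the run constraint is only meaningful when both lexicalities occur
    single_lex <- length(unique(tr$lexicality)) < 2
    for (attempt in seq_len(max_retries)) {
      ord <- sample.int(nrow(tr))
      if (single_lex || .max_run(tr$lexicality[ord]) <= max_lex_run) {
        tr <- tr[ord, ]
        tr$position <- seq_len(nrow(tr))
        return(tr)
      }
    }
    stop(sprintf(paste0("could not satisfy the lexicality-run constraint ",
                        "(max %d adjacent equal-lexicality targets) in block ",
                        "%d after %d retries"), max_lex_run, b, max_retries),
         call. = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[, c("block", "position", "prime", "target", "condition",
                 "lexicality")]
  rownames(out) <- NULL
  structure(out, participant = as.integer(participant),
            n_blocks = as.integer(n_blocks), seed = as.integer(seed),
            class = c("session_design", "data.frame"))
}

#' Check a session design against its invariants
#'
#' Verifies by exhaustive scan that (1) all blocks have equal trial counts,
#' (2) each critical target occurs exactly once per critical condition,
#' (3) no critical target occurs in adjacent blocks, and (4) no more than
#' `max_lex_run` adjacent trials within a block share target lexicality.
#'
#' @param design A `session_design`.
#' @param max_lex_run Allowed lexicality run length.
#' @return Invisibly `TRUE`; stops with a message naming the violated
#'   invariant otherwise.
#' @export
validate_session <- function(design, max_lex_run = 4L) {
  stopifnot(inherits(design, "session_design"))
  counts <- table(design$block)
  if (length(unique(as.integer(counts))) != 1) {
    stop("blocks have unequal trial counts", call. = FALSE)
  }
  crit <- design[design$condition %in% critical_conditions(), ]
  inc <- table(crit$target, crit$condition)
  if (!all(inc == 1)) {
    stop("target x condition incidence is not all-ones", call. = FALSE)
  }
  for (tg in unique(crit$target)) {
    b <- sort(unique(crit$block[crit$target == tg]))
    if (any(diff(b) < 2)) {
      stop(sprintf("critical target %s occurs in adjacent blocks", tg),
           call. = FALSE)
    }
  }
  ord <- order(design$block, design$position)
  runs <- tapply(design$lexicality[ord], design$block[ord], function(x) {
    if (length(unique(x)) < 2) 0L else .max_run(x)
  })
  if (any(runs > max_lex_run)) {
    stop(sprintf("a block contains more than %d adjacent equal-lexicality targets",
                 max_lex_run), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a session design
#'
#' Serializes the trial list as tab-separated text (one row per trial:
#' block, position, prime, target, condition, lexicality) preceded by a
#' one-line JSON header carrying participant, block count and seed.
#'
#' @param design A `session_design`.
#' @param path Output file.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed `session_design`.
#' @export
write_session <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  header <- jsonlite::toJSON(list(format = "erpperm-session", version = 1L,
                                  participant = attr(design, "participant"),
                                  n_blocks = attr(design, "n_blocks"),
                                  seed = attr(design, "seed")),
                             auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  utils::write.table(as.data.frame(design), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) {
    stop("not a session file: missing JSON header line", call. = FALSE)
  }
  header <- jsonlite::fromJSON(sub("^#", "", first))
  if (is.null(header$format) || header$format != "erpperm-session") {
    stop("not a session file: header field 'format' missing or wrong",
         call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE)
  structure(df, participant = header$participant, n_blocks = header$n_blocks,
            seed = header$seed, class = c("session_design", "data.frame"))
}
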