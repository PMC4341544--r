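# Electrode montage and the 61 -> 19 pooling map.

#' Default electrode pooling map (10-20 subset)
#'
#' The shipped map pools the 61-channel recording montage to the 19 standard
#' electrodes of the 10-20 system, each pooled electrode being the unweighted
#' mean of three adjacent recording electrodes (Fpz from Fp1/Fpz/Fp2, and so
#' on). Returned as a named list: pooled label -> character vector of the
#' three member labels.
#'
#' @return A named list of length 19 with class `pooling_map`.
#' @export
default_pooling_map <- function() {
  if (is.null(.erpperm_cache$pooling_map)) {
    path <- system.file("extdata", "pooling_10_20.json", package = "erpperm",
                        mustWork = TRUE)
    .erpperm_cache$pooling_map <- read_pooling_map(path)
  }
  .erpperm_cache$pooling_map
}

.erpperm_cache <- new.env(parent = emptyenv())

#' Read and validate a pooling map from JSON
#'
#' @param path JSON file with a `pools` object mapping pooled labels to
#'   arrays of member channel labels.
#' @return A named list with class `pooling_map`.
#' @export
read_pooling_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$pools)) {
    stop("pooling map file lacks a 'pools' field", call. = FALSE)
  }
  map <- lapply(obj$pools, as.character)
  validate_pooling_map(map)
  structure(map, class = "pooling_map")
}

#' @rdname read_pooling_map
#' @param map A named list: pooled label -> member channel labels.
#' @export
validate_pooling_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("every pool must be named", call. = FALSE)
  }
  sizes <- lengths(map)
  if (any(sizes != 3)) {
    stop("each pooled electrode must comprise exactly 3 recording electrodes",
         call. = FALSE)
  }
  raw <- unlist(map, use.names = FALSE)
  if (anyDuplicated(raw)) {
    stop("recording electrodes must be disjoint across pools", call. = FALSE)
  }
  invisible(TRUE)
}

#' Standard pooled channel labels
#' @return The 19 pooled labels of [default_pooling_map()], in map order.
#' @export
standard_channels <- function() names(default_pooling_map())

#' Default 61-channel recording montage
#'
#' The 57 electrodes referenced by the default pooling map plus four
#' temporal/mastoid-adjacent sites (FT9, FT10, TP9, TP10) that do not enter
#' any pool.
#'
#' @return Character vector of 61 channel labels.
#' @export
default_montage <- function() {
  c(unlist(default_pooling_map(), use.names = FALSE),
    "FT9", "FT10", "TP9", "TP10")
}

# map a raw channel label to its pooled parent (NA if unpooled)
.pool_parent <- function(channels, map = default_pooling_map()) {
  parents <- rep(names(map), lengths(map))
  names(parents) <- unlist(map, use.names = FALSE)
  out <- parents[channels]
  out[channels %in% names(map)] <- channels[channels %in% names(map)]
  unname(out)
}
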