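# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parse a presence/absence pattern
#'
#' Accepts a bit string such as `"1101100110000"`, a logical vector, or a
#' 0/1 numeric vector, and returns a logical vector.
#'
#' @param pattern bit string, logical or 0/1 numeric vector.
#' @param width expected width; checked when given.
#' @return logical vector.
#' @export
#' @examples
#' parse_pattern("10110")
parse_pattern <- function(pattern, width = NULL) {
  if (is.character(pattern) && length(pattern) == 1L) {
    chars <- strsplit(pattern, "")[[1]]
    if (!all(chars %in% c("0", "1"))) {
      stop("pattern string must contain only '0' and '1'")
    }
    bits <- chars == "1"
  } else if (is.logical(pattern)) {
    bits <- pattern
  } else if (is.numeric(pattern) && all(pattern %in% c(0, 1))) {
    bits <- pattern == 1
  } else {
    stop("pattern must be a bit string, logical or 0/1 vector")
  }
  if (!is.null(width) && length(bits) != width) {
    stop(sprintf("pattern has width %d, expected %d", length(bits), width))
  }
  bits
}

#' Format a logical vector as a bit string
#' @param bits logical vector.
#' @return character scalar such as `"1101100110000"`.
#' @export
pattern_string <- function(bits) {
  paste(as.integer(bits), collapse = "")
}

# Hamming distance between each row of a logical matrix and a pattern.
hamming_to_pattern <- function(mat, bits) {
  stopifnot(ncol(mat) == length(bits))
  rowSums(mat != matrix(bits, nrow(mat), length(bits), byrow = TRUE))
}
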