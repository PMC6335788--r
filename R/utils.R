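# Shared helpers: amino-acid alphabet checks and seeded execution.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes of the 20 standard amino acids, used to validate
#' protein sequences throughout the package. `X` (unknown residue) is
#' accepted in input proteins but never matches a motif position.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Split a sequence string into single characters
#' @param x a length-1 character string
#' @return character vector of single letters
#' @keywords internal
#' @noRd
seq_chars <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  strsplit(x, "", fixed = TRUE)[[1L]]
}

#' Validate an amino-acid string
#' @param x sequence string (or character vector of residues)
#' @param allow_x allow the ambiguity letter X
#' @param what label used in error messages
#' @keywords internal
#' @noRd
check_aa <- function(x, allow_x = FALSE, what = "sequence") {
  ch <- if (length(x) == 1L && nchar(x[1L]) != 1L) seq_chars(x) else x
  alphabet <- if (allow_x) c(AA_STANDARD, "X") else AA_STANDARD
  bad <- setdiff(unique(ch), alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid letter(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(ch)
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All synthetic-data generators route their randomness through this helper so
#' that a given seed yields byte-identical output regardless of what the
#' caller's RNG was doing.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
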