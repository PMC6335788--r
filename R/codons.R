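# Codon-level helpers shared by the synthetic generator and the Ka/Ks
# estimator. The standard nuclear genetic code is taken from Biostrings.

#' @importFrom Biostrings GENETIC_CODE
codon_table <- function() Biostrings::GENETIC_CODE

# cached lookups, built on first use
.codon_env <- new.env(parent = emptyenv())

codon_aa <- function() {
  if (is.null(.codon_env$aa)) .codon_env$aa <- codon_table()
  .codon_env$aa
}

#' Sense (non-stop) codons of the standard genetic code
#' @return character vector of 61 codons
#' @export
sense_codons <- function() {
  aa <- codon_aa()
  names(aa)[aa != "*"]
}

#' Codons encoding each amino acid (standard code)
#' @return named list, one character vector of codons per amino-acid letter
#' @keywords internal
#' @noRd
codons_by_aa <- function() {
  if (is.null(.codon_env$by_aa)) {
    aa <- codon_aa()
    .codon_env$by_aa <- split(names(aa), aa)
  }
  .codon_env$by_aa
}

#' Split a CDS string into codons
#' @param cds coding sequence (A/C/G/T), length divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length is not divisible by 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a CDS string with the standard genetic code
#' @param cds coding sequence, length divisible by 3
#' @return amino-acid string ("*" for stop codons)
#' @export
translate_cds <- function(cds) {
  paste(unname(codon_aa()[split_codons(toupper(cds))]), collapse = "")
}

#' Reverse-translate a protein with seeded uniform codon choice
#'
#' Each residue is encoded by a codon drawn uniformly at random among its
#' synonymous codons. Codon identity only matters downstream for Ka/Ks
#' simulations, where divergence is controlled explicitly, so a uniform
#' choice is adequate and keeps the generator simple and reproducible.
#'
#' @param protein amino-acid string (no `X`, no stop)
#' @param seed integer seed
#' @return CDS string of length `3 * nchar(protein)`
#' @export
reverse_translate <- function(protein, seed) {
  ch <- check_aa(protein, allow_x = FALSE, what = "protein")
  by_aa <- codons_by_aa()
  with_seed(seed, {
    codons <- vapply(ch, function(a) {
      cs <- by_aa[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    paste(codons, collapse = "")
  })
}

#' @keywords internal
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
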