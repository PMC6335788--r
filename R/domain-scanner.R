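# bZIP domain detection.
#
# Position convention (no position 0): the basic region spans domain
# positions -25..-10 (16 residues), the hinge spans -9..-1 (9 residues) and
# the leucine zipper starts at +1. The invariant asparagine sits at -18 and
# the invariant arginine/lysine at -10, nine residues upstream of the first
# zipper leucine. With a 1-based anchor index `a` (the Asn at -18):
#   index(-10) = a + 8, index(+1) = a + 18, index(-25) = a - 7.

#' Scan a protein for bZIP domains
#'
#' Detects the invariant basic-region motif N-x7-R/K followed, nine residues
#' later, by a leucine heptad repeat. A hit at 1-based index `i` requires
#' `N` at `i`, `R` or `K` at `i + 8` (also `I` when `relaxed = TRUE`, to
#' admit the rare isoleucine substitution seen in some family members), `L`
#' at `i + 18`, and at least `min_heptads - 1` further leucines spaced 7
#' apart (`i + 18 + 7k`). `X` never matches a motif position.
#'
#' @param protein amino-acid string, or a named list/data.frame row with
#'   `id` and `sequence`
#' @param id protein identifier used in the annotation (ignored when
#'   `protein` carries its own `id`)
#' @param relaxed also accept `I` at the -10 position
#' @param min_heptads minimum number of leucine heptads anchoring the zipper
#' @param max_heptads cap on the zipper length, in heptads, used for the
#'   reported zipper span
#' @return a data.frame with one row per detected domain and columns
#'   `protein_id`, `anchor_n` (1-based index of the Asn at -18),
#'   `minus18`, `minus10`, `variant_class`, `basic_start`, `basic_truncated`,
#'   `zipper_start` (1-based index of position +1), `zipper_end`,
#'   `n_heptads` (`ceiling(zipper length / 7)`). Zero rows when nothing is
#'   found; rows are ordered by `anchor_n`.
#' @export
#' @examples
#' scan_domain(strrep("A", 100))              # no Asn anywhere: zero rows
scan_domain <- function(protein, id = "protein", relaxed = FALSE,
                        min_heptads = 2L, max_heptads = 8L) {
  if (is.list(protein)) {
    if (!is.null(protein$id)) id <- protein$id
    protein <- protein$sequence
  }
  ch <- check_aa(protein, allow_x = TRUE, what = "protein")
  n <- length(ch)
  if (n == 0L) stop("empty protein sequence", call. = FALSE)
  stopifnot(min_heptads >= 1L)

  allowed10 <- if (relaxed) c("R", "K", "I") else c("R", "K")
  # the last leucine required by min_heptads must fit
  last_req <- 18L + 7L * (min_heptads - 1L)
  hits <- integer(0)
  if (n > last_req) {
    cand <- which(ch == "N")
    cand <- cand[cand + last_req <= n]
    for (i in cand) {
      if (!(ch[i + 8L] %in% allowed10)) next
      ks <- i + 18L + 7L * (0:(min_heptads - 1L))
      if (all(ch[ks] == "L")) hits <- c(hits, i)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(protein_id = character(0), anchor_n = integer(0),
                      minus18 = character(0), minus10 = character(0),
                      variant_class = character(0), basic_start = integer(0),
                      basic_truncated = logical(0), zipper_start = integer(0),
                      zipper_end = integer(0), n_heptads = integer(0),
                      stringsAsFactors = FALSE))
  }
  minus10 <- ch[hits + 8L]
  zs <- hits + 18L
  ze <- pmin(n, zs + 7L * max_heptads - 1L)
  data.frame(
    protein_id = id,
    anchor_n = hits,
    minus18 = ch[hits],
    minus10 = minus10,
    variant_class = classify_binding_variant(ch[hits], minus10),
    basic_start = pmax(1L, hits - 7L),
    basic_truncated = hits - 7L < 1L,
    zipper_start = zs,
    zipper_end = ze,
    n_heptads = as.integer(ceiling((ze - zs + 1L) / 7)),
    stringsAsFactors = FALSE
  )
}

#' Classify the DNA-binding-site variant of a bZIP domain
#'
#' The residues at domain positions -18 and -10 determine DNA-binding
#' specificity. `canonical_R` is the N/R configuration; `variant_K` carries
#' lysine at -10 (characteristic of one phylogenetic group); `variant_I`
#' carries the binding-incompetent isoleucine substitution at -10; anything
#' else is `noncanonical`. Total over the full residue grid and vectorized.
#'
#' @param minus18,minus10 residues at the -18 and -10 positions
#' @return character vector of variant classes
#' @export
#' @examples
#' classify_binding_variant("N", "R")  # "canonical_R"
#' classify_binding_variant("N", "K")  # "variant_K"
classify_binding_variant <- function(minus18, minus10) {
  stopifnot(length(minus18) == length(minus10))
  out <- rep("noncanonical", length(minus10))
  out[minus10 == "I"] <- "variant_I"
  out[minus18 == "N" & minus10 == "R"] <- "canonical_R"
  out[minus18 == "N" & minus10 == "K"] <- "variant_K"
  out
}

#' Extract the basic, hinge and zipper regions of an annotated domain
#'
#' @param ann one row of a [scan_domain()] annotation (data.frame or list)
#' @param protein the protein sequence the annotation belongs to
#' @param max_heptads zipper cap in heptads
#' @return list with `basic` (up to 16 residues, positions -25..-10;
#'   truncated at the sequence start when the anchor sits too close to it),
#'   `hinge` (9 residues, -9..-1), `zipper` (from +1 to at most
#'   `7 * max_heptads` residues) and `basic_truncated`
#' @export
extract_regions <- function(ann, protein, max_heptads = 8L) {
  if (is.data.frame(ann)) {
    stopifnot(nrow(ann) == 1L)
    ann <- as.list(ann)
  }
  n <- nchar(protein)
  a <- ann$anchor_n
  if (a < 1L || a + 18L > n) stop("annotation out of bounds", call. = FALSE)
  basic_start <- max(1L, a - 7L)
  list(
    basic = substr(protein, basic_start, a + 8L),
    hinge = substr(protein, a + 9L, a + 17L),
    zipper = substr(protein, a + 18L, min(n, a + 18L + 7L * max_heptads - 1L)),
    basic_truncated = a - 7L < 1L
  )
}

#' Scan a set of proteins and bind the annotations
#'
#' @param proteins named character vector of protein sequences (names are
#'   protein ids), or a `Biostrings::AAStringSet`
#' @inheritParams scan_domain
#' @param first_only keep only the most N-terminal domain per protein
#' @return data.frame of annotations (see [scan_domain()])
#' @export
scan_domains <- function(proteins, relaxed = FALSE, min_heptads = 2L,
                         max_heptads = 8L, first_only = FALSE) {
  if (methods::is(proteins, "XStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
  res <- lapply(seq_along(proteins), function(i) {
    scan_domain(proteins[[i]], id = ids[i], relaxed = relaxed,
                min_heptads = min_heptads, max_heptads = max_heptads)
  })
  out <- do.call(rbind, res)
  if (first_only && nrow(out) > 0L) {
    out <- out[!duplicated(out$protein_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
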