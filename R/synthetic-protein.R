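# Synthetic bZIP-like proteins with known domain anatomy.

#' Specify a synthetic bZIP domain
#'
#' Builds and validates the blueprint for one synthetic protein: a
#' 16-residue basic region (domain positions -25..-10) carrying the
#' invariant asparagine at -18 and R/K (or a chosen variant) at -10, a
#' 9-residue hinge (-9..-1), a leucine zipper given as 7-residue heptads
#' starting at +1, and random flanks.
#'
#' @param residue_at_minus18 residue planted at -18 (default `"N"`)
#' @param residue_at_minus10 residue planted at -10 (`"R"` by default; use
#'   `"K"` or `"I"` for the variant classes)
#' @param basic_residues 16 residues for positions -25..-10; positions 8 and
#'   16 must equal `residue_at_minus18` and `residue_at_minus10`
#' @param hinge_residues 9 residues for positions -9..-1
#' @param zipper_heptads character vector of 7-letter heptads; the first
#'   letter of each heptad lands on a zipper `d` position (+1, +8, ...)
#' @param n_flank_left,n_flank_right lengths of random flanking sequence
#' @param seed integer seed driving the flanks
#' @return object of class `domain_spec`
#' @export
domain_spec <- function(residue_at_minus18 = "N", residue_at_minus10 = "R",
                        basic_residues = NULL, hinge_residues = NULL,
                        zipper_heptads = c("LQALEKE", "LAQLEWK"),
                        n_flank_left = 0L, n_flank_right = 0L, seed = 1L) {
  check_aa(residue_at_minus18, what = "residue_at_minus18")
  check_aa(residue_at_minus10, what = "residue_at_minus10")
  if (is.null(basic_residues)) {
    basic_residues <- seq_chars("MKRERRK.KSAERSR.")
    basic_residues[8L] <- residue_at_minus18
    basic_residues[16L] <- residue_at_minus10
  }
  if (length(basic_residues) == 1L) basic_residues <- seq_chars(basic_residues)
  if (is.null(hinge_residues)) hinge_residues <- seq_chars("RKVSAQRSR")
  if (length(hinge_residues) == 1L) hinge_residues <- seq_chars(hinge_residues)
  check_aa(basic_residues, what = "basic_residues")
  check_aa(hinge_residues, what = "hinge_residues")
  if (length(basic_residues) != 16L)
    stop("basic_residues must hold 16 residues (-25..-10)", call. = FALSE)
  if (length(hinge_residues) != 9L)
    stop("hinge_residues must hold 9 residues (-9..-1)", call. = FALSE)
  if (basic_residues[8L] != residue_at_minus18)
    stop("basic_residues[8] must equal residue_at_minus18", call. = FALSE)
  if (basic_residues[16L] != residue_at_minus10)
    stop("basic_residues[16] must equal residue_at_minus10", call. = FALSE)
  if (length(zipper_heptads) < 1L || any(nchar(zipper_heptads) != 7L))
    stop("every zipper heptad must have exactly 7 residues", call. = FALSE)
  for (h in zipper_heptads) check_aa(h, what = "zipper heptad")
  stopifnot(n_flank_left >= 0L, n_flank_right >= 0L)
  structure(list(residue_at_minus18 = residue_at_minus18,
                 residue_at_minus10 = residue_at_minus10,
                 basic_residues = basic_residues,
                 hinge_residues = hinge_residues,
                 zipper_heptads = zipper_heptads,
                 n_flank_left = as.integer(n_flank_left),
                 n_flank_right = as.integer(n_flank_right),
                 seed = as.integer(seed)),
            class = "domain_spec")
}

#' Generate a protein with a planted bZIP domain
#'
#' Assembles `flank_left + basic(16) + hinge(9) + zipper + flank_right` and
#' returns the sequence together with its ground-truth annotation in the
#' same layout that [scan_domain()] produces. Flanks are drawn from the
#' 19-letter alphabet excluding asparagine, so a motif-bearing anchor can
#' only occur where one was planted.
#'
#' @param spec a [domain_spec()]
#' @param id protein id recorded in the annotation
#' @return list with `sequence` and `annotation` (1-row data.frame)
#' @export
#' @examples
#' p <- make_domain_protein(domain_spec(n_flank_left = 10, seed = 42))
#' scan_domain(p$sequence)$anchor_n == p$annotation$anchor_n
make_domain_protein <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "domain_spec"))
  flank_alphabet <- setdiff(AA_STANDARD, "N")
  flanks <- with_seed(spec$seed, list(
    left = paste(sample(flank_alphabet, spec$n_flank_left, replace = TRUE),
                 collapse = ""),
    right = paste(sample(flank_alphabet, spec$n_flank_right, replace = TRUE),
                  collapse = "")
  ))
  zipper <- paste(spec$zipper_heptads, collapse = "")
  sequence <- paste0(flanks$left, paste(spec$basic_residues, collapse = ""),
                     paste(spec$hinge_residues, collapse = ""), zipper,
                     flanks$right)
  anchor <- spec$n_flank_left + 8L            # index of the -18 residue
  zlen <- nchar(zipper)
  annotation <- data.frame(
    protein_id = id,
    anchor_n = anchor,
    minus18 = spec$residue_at_minus18,
    minus10 = spec$residue_at_minus10,
    variant_class = classify_binding_variant(spec$residue_at_minus18,
                                             spec$residue_at_minus10),
    basic_start = spec$n_flank_left + 1L,
    basic_truncated = FALSE,
    zipper_start = anchor + 18L,
    zipper_end = anchor + 18L + zlen - 1L,
    n_heptads = as.integer(ceiling(zlen / 7)),
    stringsAsFactors = FALSE
  )
  list(sequence = sequence, annotation = annotation)
}

#' Draw a random domain blueprint
#'
#' Convenience generator for property-style testing: random basic, hinge and
#' zipper content from the alphabet excluding asparagine and leucine (so the
#' only Asn is the planted -18 anchor and the only heptad-spaced leucines
#' are the planted `d` positions), leucine at the start of every heptad, and
#' random flank lengths.
#'
#' @param seed integer seed
#' @param max_flank maximum flank length on either side
#' @param n_heptads_range range of zipper heptad counts
#' @param minus10_choices residues to sample for the -10 position
#' @return a [domain_spec()]
#' @export
random_domain_spec <- function(seed, max_flank = 100L,
                               n_heptads_range = c(2L, 6L),
                               minus10_choices = c("R", "K")) {
  with_seed(seed, {
    bg <- setdiff(AA_STANDARD, c("N", "L"))
    m10 <- sample(minus10_choices, 1L)
    basic <- sample(bg, 16L, replace = TRUE)
    basic[8L] <- "N"
    basic[16L] <- m10
    hinge <- sample(bg, 9L, replace = TRUE)
    nh <- sample(seq(n_heptads_range[1L], n_heptads_range[2L]), 1L)
    heptads <- vapply(seq_len(nh), function(i) {
      paste(c("L", sample(bg, 6L, replace = TRUE)), collapse = "")
    }, character(1))
    domain_spec(residue_at_minus18 = "N", residue_at_minus10 = m10,
                basic_residues = basic, hinge_residues = hinge,
                zipper_heptads = heptads,
                n_flank_left = sample(0:max_flank, 1L),
                n_flank_right = sample(0:max_flank, 1L),
                seed = sample.int(.Machine$integer.max, 1L))
  })
}
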