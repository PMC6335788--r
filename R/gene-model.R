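# Gene models, CDS coordinate maps, intron splicing phases and the
# basic/hinge intron pattern classes.
#
# Splicing phase convention: phase 0 (P0) introns fall between codons
# (after the third nucleotide), P1 after the first nucleotide of a codon,
# P2 after the second. A P0 intron between codon p and codon p+1 is
# labelled with residue p; P1/P2 introns with the residue whose codon they
# interrupt.

#' Construct a gene model
#'
#' @param gene_id gene identifier
#' @param exons data.frame with `start` and `end` (1-based, inclusive,
#'   genomic) listing the CDS-carrying exons in transcription order:
#'   ascending coordinates on `+`, descending on `-`
#' @param strand `"+"` or `"-"`
#' @param chrom chromosome/scaffold id
#' @param protein_id linked protein id
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_id, exons, strand = "+", chrom = "chr1",
                       protein_id = gene_id) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon", call. = FALSE)
  if (any(exons$end < exons$start)) stop("exon end < start", call. = FALSE)
  ord <- order(exons$start)
  sorted <- exons[ord, , drop = FALSE]
  if (nrow(sorted) > 1L &&
      any(sorted$start[-1L] <= sorted$end[-nrow(sorted)]))
    stop("overlapping exons", call. = FALSE)
  in_tx_order <- if (strand == "+") !is.unsorted(exons$start, strictly = TRUE)
                 else !is.unsorted(rev(exons$start), strictly = TRUE)
  if (!in_tx_order)
    stop("exons must be listed in transcription order", call. = FALSE)
  cds_len <- sum(exons$end - exons$start + 1L)
  if (cds_len %% 3L != 0L)
    stop("total CDS length is not divisible by 3", call. = FALSE)
  structure(list(gene_id = gene_id, protein_id = protein_id, chrom = chrom,
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s) %d exon(s), CDS %d nt\n", x$gene_id,
              x$chrom, x$strand, nrow(x$exons),
              sum(x$exons$end - x$exons$start + 1L)))
  invisible(x)
}

#' Build the CDS <-> genomic coordinate map of a gene model
#'
#' The map is a bijection between CDS nucleotide positions 1..L and the
#' genomic positions of the CDS-carrying exon bases, traversed in
#' transcription order (minus-strand exons are walked from high to low
#' coordinates). Protein residue p corresponds to CDS nucleotides
#' 3p-2..3p.
#'
#' @param model a [gene_model()]
#' @return object of class `cds_map` with elements `cds2gen` (integer
#'   vector, genomic position of every CDS nucleotide) and `model`
#' @export
build_cds_map <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  cds2gen <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    if (model$strand == "+") s:e else e:s
  }), use.names = FALSE)
  structure(list(cds2gen = cds2gen, model = model), class = "cds_map")
}

#' @rdname build_cds_map
#' @param map a `cds_map`
#' @param pos CDS nucleotide position(s)
#' @export
cds_to_genomic <- function(map, pos) {
  stopifnot(inherits(map, "cds_map"), all(pos >= 1L),
            all(pos <= length(map$cds2gen)))
  map$cds2gen[pos]
}

#' @rdname build_cds_map
#' @param gpos genomic position(s); must lie in a CDS exon
#' @export
genomic_to_cds <- function(map, gpos) {
  idx <- match(gpos, map$cds2gen)
  if (anyNA(idx)) stop("genomic position not in CDS", call. = FALSE)
  idx
}

#' @rdname build_cds_map
#' @param residue protein residue index (1-based)
#' @return for `protein_to_cds`, an integer matrix with columns
#'   `first`..`third` of CDS positions per residue
#' @export
protein_to_cds <- function(residue) {
  stopifnot(all(residue >= 1L))
  cbind(first = 3L * residue - 2L, second = 3L * residue - 1L,
        third = 3L * residue)
}

#' Locate introns and compute their splicing phases
#'
#' One record per inter-exon gap, in transcription order. The phase is the
#' count of CDS nucleotides preceding the intron modulo 3; the protein
#' position is the residue the junction interrupts (P1/P2) or the residue
#' immediately upstream (P0). Phases recorded in a GFF3 file are never
#' trusted; everything is recomputed from exon lengths.
#'
#' @param model a [gene_model()]
#' @return data.frame with columns `index`, `cds_offset`, `phase`,
#'   `protein_pos`, `domain_pos` (NA until
#'   [annotate_domain_positions()] is applied) and `region`
#' @export
locate_introns <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  lens <- model$exons$end - model$exons$start + 1L
  n_int <- length(lens) - 1L
  if (n_int < 1L) {
    return(data.frame(index = integer(0), cds_offset = integer(0),
                      phase = integer(0), protein_pos = integer(0),
                      domain_pos = integer(0), region = character(0),
                      stringsAsFactors = FALSE))
  }
  offs <- cumsum(lens)[seq_len(n_int)]
  phase <- offs %% 3L
  data.frame(index = seq_len(n_int), cds_offset = offs, phase = phase,
             protein_pos = as.integer(ifelse(phase == 0L, offs %/% 3L,
                                             ceiling(offs / 3))),
             domain_pos = NA_integer_, region = NA_character_,
             stringsAsFactors = FALSE)
}

#' Assign domain-relative positions and regions to introns
#'
#' Introns whose junction residue lies within domain positions -25..-1 get
#' a `domain_pos` and a region: `basic` for -25..-10, `hinge` for -9..-1;
#' all other introns are `outside`.
#'
#' @param introns output of [locate_introns()]
#' @param ann the [scan_domain()] annotation (1 row) of the same protein
#' @param protein_id optional id cross-check against `ann$protein_id`
#' @return `introns` with `domain_pos` and `region` filled
#' @export
annotate_domain_positions <- function(introns, ann, protein_id = NULL) {
  if (is.data.frame(ann)) {
    stopifnot(nrow(ann) == 1L)
    ann <- as.list(ann)
  }
  if (!is.null(protein_id) && !identical(protein_id, ann$protein_id))
    stop("annotation belongs to a different protein", call. = FALSE)
  dp <- introns$protein_pos - ann$anchor_n - 18L
  inside <- dp >= -25L & dp <= -1L
  introns$domain_pos <- ifelse(inside, dp, NA_integer_)
  introns$region <- ifelse(!inside, "outside",
                           ifelse(dp <= -10L, "basic", "hinge"))
  introns
}

#' Classify the basic/hinge intron pattern of a gene
#'
#' Four canonical configurations of introns within the basic+hinge window
#' are distinguished: `a` — exactly one P0 intron at hinge position -5;
#' `b` — exactly two P0 introns, one in the basic region and one in the
#' hinge; `c` — exactly one P2 intron at basic position -20; `d` — no
#' intron in the window at all. Genes matching none of these are reported
#' as `other` rather than forced into a class.
#'
#' @param introns annotated intron records (see
#'   [annotate_domain_positions()]); introns outside the window are ignored
#' @return one of `"a"`, `"b"`, `"c"`, `"d"`, `"other"`
#' @export
#' @examples
#' classify_pattern(data.frame(region = character(0)))  # "d"
classify_pattern <- function(introns) {
  win <- introns[!is.na(introns$region) &
                 introns$region %in% c("basic", "hinge"), , drop = FALSE]
  n <- nrow(win)
  if (n == 0L) return("d")
  if (n == 1L) {
    if (win$phase == 0L && win$region == "hinge" && win$domain_pos == -5L)
      return("a")
    if (win$phase == 2L && win$region == "basic" && win$domain_pos == -20L)
      return("c")
    return("other")
  }
  if (n == 2L && all(win$phase == 0L) &&
      setequal(win$region, c("basic", "hinge")))
    return("b")
  "other"
}
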