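# Synthetic gene models: reverse-translated CDS with introns planted at
# chosen protein/domain positions and phases.

#' Plan intron placement for a synthetic gene
#'
#' @param positions integer vector: domain positions (-25..-1, resolved via
#'   a domain annotation) or 1-based protein residue indices; must resolve
#'   to strictly increasing CDS offsets
#' @param phases matching vector of splicing phases (0, 1 or 2)
#' @param intron_lengths optional intron lengths (recycled); when `NULL`,
#'   lengths are drawn uniformly from 60..200 nt
#' @return object of class `intron_plan`
#' @export
intron_plan <- function(positions = integer(0), phases = integer(0),
                        intron_lengths = NULL) {
  stopifnot(length(positions) == length(phases),
            all(phases %in% c(0L, 1L, 2L)))
  if (!is.null(intron_lengths)) stopifnot(all(intron_lengths >= 4L))
  structure(list(positions = as.integer(positions),
                 phases = as.integer(phases),
                 intron_lengths = intron_lengths),
            class = "intron_plan")
}

#' Generate a gene model for a protein with planted introns
#'
#' The protein is reverse-translated with a seeded uniform codon choice,
#' the CDS is cut at the planned positions/phases, and random introns with
#' canonical `GT..AG` ends are inserted. The concatenated exon CDS always
#' retranslates to the input protein. Negative plan positions are
#' interpreted as bZIP-domain positions and require `annotation`.
#'
#' @param protein amino-acid string
#' @param plan an [intron_plan()]
#' @param seed integer seed (codon choice and intron sequences)
#' @param annotation [scan_domain()] annotation of `protein`, needed only
#'   when the plan uses domain-relative positions
#' @param gene_id,chrom,strand,gene_start placement of the gene; the gene
#'   occupies `gene_start` onward on `chrom`
#' @param protein_id id stored in the model
#' @return list with `cds` (spliced CDS string), `model` (a
#'   [gene_model()]), `introns` (ground-truth records in the
#'   [locate_introns()] layout, domain-annotated when `annotation` is
#'   given), `intron_sequences`, `gene_sequence` (transcript-oriented
#'   exon+intron sequence) and `genomic_sequence` (chromosome-forward)
#' @export
make_gene_model <- function(protein, plan = intron_plan(), seed = 1L,
                            annotation = NULL, gene_id = "gene1",
                            chrom = "chr1", strand = "+", gene_start = 1L,
                            protein_id = gene_id) {
  stopifnot(inherits(plan, "intron_plan"))
  ch <- check_aa(protein, allow_x = FALSE, what = "protein")
  n_res <- length(ch)

  # resolve plan positions to residue indices
  res_idx <- vapply(plan$positions, function(p) {
    if (p < 0L) {
      if (is.null(annotation))
        stop("domain-relative intron positions need an annotation",
             call. = FALSE)
      if (p < -25L) stop("domain position below -25", call. = FALSE)
      a <- if (is.data.frame(annotation)) annotation$anchor_n[1L]
           else annotation$anchor_n
      a + 18L + p
    } else if (p == 0L) {
      stop("there is no domain position 0", call. = FALSE)
    } else as.integer(p)
  }, integer(1))
  if (any(res_idx < 1L) || any(res_idx > n_res))
    stop("intron planted beyond the protein", call. = FALSE)
  offsets <- ifelse(plan$phases == 0L, 3L * res_idx,
                    3L * (res_idx - 1L) + plan$phases)
  if (is.unsorted(offsets, strictly = TRUE))
    stop("intron positions must be strictly increasing", call. = FALSE)
  if (length(offsets) > 0L && offsets[length(offsets)] >= 3L * n_res)
    stop("intron planted beyond protein end", call. = FALSE)

  by_aa <- codons_by_aa()
  pieces <- with_seed(seed, {
    codons <- vapply(ch, function(a) {
      cs <- by_aa[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    cds <- paste(codons, collapse = "")
    n_int <- length(offsets)
    lens <- if (n_int == 0L) integer(0)
            else if (is.null(plan$intron_lengths))
              sample(60:200, n_int, replace = TRUE)
            else rep_len(plan$intron_lengths, n_int)
    intron_seqs <- vapply(lens, function(L) {
      paste0("GT", random_dna(L - 4L), "AG")
    }, character(1))
    list(cds = cds, intron_seqs = intron_seqs)
  })
  cds <- pieces$cds
  cuts <- c(0L, offsets, nchar(cds))
  exon_seqs <- substring(cds, cuts[-length(cuts)] + 1L, cuts[-1L])
  gene_sequence <- paste(
    c(rbind(exon_seqs, c(pieces$intron_seqs, "")))[seq_len(2L * length(exon_seqs) - 1L)],
    collapse = "")

  # transcript-oriented exon intervals within the gene sequence
  exon_len <- nchar(exon_seqs)
  intron_len <- nchar(pieces$intron_seqs)
  tx_start <- cumsum(c(1L, utils::head(exon_len, -1L) +
                             intron_len))
  tx_end <- tx_start + exon_len - 1L
  gene_len <- nchar(gene_sequence)
  if (strand == "+") {
    ex <- data.frame(start = gene_start + tx_start - 1L,
                     end = gene_start + tx_end - 1L)
    genomic_sequence <- gene_sequence
  } else {
    ex <- data.frame(start = gene_start + gene_len - tx_end,
                     end = gene_start + gene_len - tx_start)
    genomic_sequence <- revcomp(gene_sequence)
  }
  model <- gene_model(gene_id, ex, strand = strand, chrom = chrom,
                      protein_id = protein_id)

  # ground truth straight from the plan (independent of locate_introns)
  truth <- data.frame(index = seq_along(offsets),
                      cds_offset = as.integer(offsets),
                      phase = plan$phases,
                      protein_pos = res_idx,
                      domain_pos = rep(NA_integer_, length(offsets)),
                      region = rep(NA_character_, length(offsets)),
                      stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    a <- if (is.data.frame(annotation)) annotation$anchor_n[1L]
         else annotation$anchor_n
    dp <- res_idx - a - 18L
    inside <- dp >= -25L & dp <= -1L
    truth$domain_pos <- ifelse(inside, dp, NA_integer_)
    truth$region <- ifelse(!inside, "outside",
                           ifelse(dp <= -10L, "basic", "hinge"))
  }
  list(cds = cds, model = model, introns = truth,
       intron_sequences = pieces$intron_seqs,
       gene_sequence = gene_sequence, genomic_sequence = genomic_sequence)
}
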