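# File input/output: FASTA via Biostrings, GFF3 via rtracklayer, plain
# TSV tables for annotations.

#' Read and write protein/CDS FASTA
#'
#' Thin wrappers around Biostrings keeping the package's working
#' representation (named character vectors) at the boundary.
#'
#' @param path FASTA file path
#' @return `read_protein_fasta`/`read_dna_fasta`: named character vector
#'   of sequences
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_protein_fasta
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_protein_fasta
#' @param seqs named character vector of sequences
#' @param type `"AA"` or `"DNA"`
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive coordinates).
#' CDS phase attributes are written for completeness but are always
#' recomputed from exon lengths when read back.
#'
#' @param model a [gene_model()]
#' @param path output file
#' @export
write_gene_model_gff3 <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  cds_len <- ex$end - ex$start + 1L
  # GFF3 phase of each CDS piece: nucleotides to skip to the next codon
  # start, in transcription order
  phase <- c(0L, (3L - cumsum(cds_len) %% 3L) %% 3L)[seq_len(nrow(ex))]
  span <- range(c(ex$start, ex$end))
  feat <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(
      start = c(span[1L], span[1L], ex$start),
      end = c(span[2L], span[2L], ex$end)),
    strand = model$strand)
  mrna_id <- paste0(model$gene_id, ".t1")
  S4Vectors::mcols(feat)$type <- c("gene", "mRNA", rep("CDS", nrow(ex)))
  S4Vectors::mcols(feat)$ID <- c(model$gene_id, mrna_id,
                                 paste0(mrna_id, ".cds", seq_len(nrow(ex))))
  S4Vectors::mcols(feat)$Parent <- c(NA, model$gene_id,
                                     rep(mrna_id, nrow(ex)))
  S4Vectors::mcols(feat)$phase <- c(NA_integer_, NA_integer_, phase)
  S4Vectors::mcols(feat)$protein_id <- c(NA, rep(model$protein_id,
                                                 nrow(ex) + 1L))
  rtracklayer::export(feat, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only `CDS` features are used; each mRNA's CDS pieces become the exons
#' of one [gene_model()], ordered in transcription order. Recorded phases
#' are ignored.
#'
#' @param path GFF3 file
#' @return named list of [gene_model()] objects (by gene id)
#' @export
read_gene_models_gff3 <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in GFF3", call. = FALSE)
  parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p) > 0L) p[[1L]] else NA_character_, character(1))
  keyed <- split(seq_along(cds), parent)
  models <- lapply(names(keyed), function(tx) {
    sub <- cds[keyed[[tx]]]
    strand <- as.character(S4Vectors::runValue(GenomicRanges::strand(sub)))[1L]
    ord <- order(GenomicRanges::start(sub),
                 decreasing = identical(strand, "-"))
    sub <- sub[ord]
    gene_id <- sub("\\.t[0-9]+$", "", tx)
    prot <- if (!is.null(sub$protein_id) && !is.na(sub$protein_id[1L]))
      sub$protein_id[1L] else gene_id
    gene_model(gene_id,
               data.frame(start = GenomicRanges::start(sub),
                          end = GenomicRanges::end(sub)),
               strand = strand,
               chrom = as.character(GenomicRanges::seqnames(sub))[1L],
               protein_id = prot)
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "gene_id"))
}

#' Write a data.frame as a TSV file
#' @param x data.frame
#' @param path output file
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
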