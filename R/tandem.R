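# Tandem-duplication cluster detection from gene order and pairwise
# similarity.

#' Find tandem-duplication clusters
#'
#' A tandem cluster holds at least two genes, consecutive in chromosome
#' order up to a tolerated number of intervening non-members, each similar
#' (e-value strictly below `threshold`) to at least one gene already in
#' the cluster. Clusters are grown greedily left to right within each
#' chromosome and never span chromosomes; only maximal clusters are
#' returned. By default one unrelated gene is tolerated per gap between
#' consecutive members (`per_cluster = TRUE` instead tolerates one per
#' cluster in total).
#'
#' @param gene_order data.frame with `gene_id`, `chrom` and `position`
#'   (any orderable position key; rank along the chromosome is what
#'   matters)
#' @param edges data.frame with `gene_a`, `gene_b`, `evalue`; pairs are
#'   unordered
#' @param threshold similarity threshold (strict `<`)
#' @param max_skip intervening non-members tolerated per gap
#' @param per_cluster apply `max_skip` per cluster instead of per gap
#' @return list of clusters; each is a list with `chrom` and `members`
#'   (gene ids in chromosome order)
#' @export
find_tandem_clusters <- function(gene_order, edges, threshold = 1e-20,
                                 max_skip = 1L, per_cluster = FALSE) {
  stopifnot(all(c("gene_id", "chrom", "position") %in% names(gene_order)))
  if (nrow(edges) > 0L) {
    stopifnot(all(c("gene_a", "gene_b", "evalue") %in% names(edges)))
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)),
                       gene_order$gene_id)
    if (length(unknown) > 0L)
      stop(sprintf("edge references unknown gene(s): %s",
                   paste(utils::head(unknown, 3L), collapse = ", ")),
           call. = FALSE)
    edges <- edges[edges$evalue < threshold, , drop = FALSE]
  }
  sim_key <- if (nrow(edges) > 0L) {
    unique(paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b), sep = "\r"))
  } else character(0)
  similar <- function(g, members) {
    any(paste(pmin(g, members), pmax(g, members), sep = "\r") %in% sim_key)
  }

  clusters <- list()
  for (chr in unique(gene_order$chrom)) {
    genes <- gene_order$gene_id[gene_order$chrom == chr]
    genes <- genes[order(gene_order$position[gene_order$chrom == chr])]
    n <- length(genes)
    i <- 1L
    while (i <= n) {
      members_idx <- i
      skipped <- 0L
      j <- i + 1L
      last <- i
      while (j <= n) {
        gap <- j - last - 1L
        budget <- if (per_cluster) max_skip - skipped else max_skip
        if (gap > budget) break
        if (similar(genes[j], genes[members_idx])) {
          members_idx <- c(members_idx, j)
          skipped <- skipped + gap
          last <- j
        }
        j <- j + 1L
      }
      if (length(members_idx) >= 2L) {
        clusters[[length(clusters) + 1L]] <-
          list(chrom = chr, members = genes[members_idx])
        i <- last + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  clusters
}
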