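# Synthetic gene-order tables with planted tandem clusters.

#' Generate a gene-order table with planted similarity clusters
#'
#' Lays `n_genes` genes along one chromosome and emits a similarity-edge
#' table in which every within-cluster pair scores an e-value strictly
#' below `1e-20` and all background edges score at or above it, so
#' [find_tandem_clusters()] can be validated against the planted truth.
#'
#' @param n_genes number of genes (ids `g1..gN`, positions `1..N`)
#' @param clusters list of disjoint integer index vectors to plant as
#'   similar groups (indices are chromosome positions)
#' @param seed integer seed
#' @param chrom chromosome id
#' @param n_background_edges random gene pairs given a non-significant
#'   e-value (>= 1e-20)
#' @return list with `gene_order` (data.frame `gene_id`, `chrom`,
#'   `position`), `edges` (data.frame `gene_a`, `gene_b`, `evalue`) and
#'   `truth` (the planted clusters as gene-id vectors)
#' @export
make_gene_order_table <- function(n_genes, clusters = list(), seed = 1L,
                                  chrom = "chr1",
                                  n_background_edges = n_genes) {
  stopifnot(n_genes >= 1L)
  if (length(clusters) > 0L) {
    idx <- unlist(clusters)
    stopifnot(all(idx >= 1L), all(idx <= n_genes))
    if (anyDuplicated(idx))
      stop("planted clusters overlap", call. = FALSE)
    if (any(vapply(clusters, length, integer(1)) < 2L))
      stop("planted clusters need at least two members", call. = FALSE)
  }
  ids <- paste0("g", seq_len(n_genes))
  gene_order <- data.frame(gene_id = ids, chrom = chrom,
                           position = seq_len(n_genes),
                           stringsAsFactors = FALSE)
  with_seed(seed, {
    edge_list <- list()
    for (cl in clusters) {
      pairs <- utils::combn(sort(cl), 2L)
      edge_list[[length(edge_list) + 1L]] <- data.frame(
        gene_a = ids[pairs[1L, ]], gene_b = ids[pairs[2L, ]],
        evalue = 10^stats::runif(ncol(pairs), -50, -21),
        stringsAsFactors = FALSE)
    }
    if (n_background_edges > 0L && n_genes >= 2L) {
      a <- sample.int(n_genes, n_background_edges, replace = TRUE)
      b <- sample.int(n_genes - 1L, n_background_edges, replace = TRUE)
      b <- ifelse(b >= a, b + 1L, b)
      edge_list[[length(edge_list) + 1L]] <- data.frame(
        gene_a = ids[pmin(a, b)], gene_b = ids[pmax(a, b)],
        evalue = 10^stats::runif(n_background_edges, -19, -1),
        stringsAsFactors = FALSE)
    }
    edges <- if (length(edge_list) > 0L) do.call(rbind, edge_list)
             else data.frame(gene_a = character(0), gene_b = character(0),
                             evalue = numeric(0), stringsAsFactors = FALSE)
    list(gene_order = gene_order, edges = edges,
         truth = lapply(clusters, function(cl) ids[sort(cl)]))
  })
}
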