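# Simulated divergence of a codon-sequence pair with controlled
# synonymous and nonsynonymous substitution loads.

#' Evolve a diverged codon-sequence pair
#'
#' Starting from one ancestral CDS, two descendant copies accumulate
#' random single-nucleotide substitutions so that the expected pairwise
#' divergence is `target_dS` synonymous substitutions per synonymous site
#' and `target_dN` nonsynonymous substitutions per nonsynonymous site
#' (sites counted as in [kaks_ng86()]). Substitution events are Poisson in
#' number, split evenly between the two lineages, and drawn uniformly over
#' the currently available changes of the required class; changes creating
#' a stop codon are rejected and resampled, so the outputs never contain
#' internal stops. Repeated hits at a site are allowed, which is what the
#' Jukes-Cantor correction in the estimator undoes.
#'
#' @param cds ancestral coding sequence; length divisible by 3, no
#'   internal stops
#' @param target_dS,target_dN expected substitutions per synonymous /
#'   nonsynonymous site (pairwise)
#' @param seed integer seed
#' @return list with `cds_a` and `cds_b`
#' @export
evolve_pair <- function(cds, target_dS, target_dN, seed = 1L) {
  stopifnot(target_dS >= 0, target_dN >= 0)
  cds <- toupper(cds)
  codons <- split_codons(cds)
  aa <- codon_aa()
  if (any(aa[codons] == "*"))
    stop("internal stop codon in input", call. = FALSE)
  sites <- ng_site_fractions()
  S <- sum(sites[codons])
  N <- 3 * length(codons) - S
  if (S == 0 && target_dS > 0)
    stop("sequence has no synonymous sites", call. = FALSE)

  mutate_lineage <- function(codons, n_syn, n_nonsyn) {
    types <- sample(c(rep("s", n_syn), rep("n", n_nonsyn)))
    for (ty in types) {
      repeat {
        i <- sample.int(length(codons), 1L)
        pos <- sample.int(3L, 1L)
        cur <- seq_chars(codons[i])
        nt <- sample(setdiff(NT, cur[pos]), 1L)
        alt <- cur; alt[pos] <- nt
        alt_cod <- paste(alt, collapse = "")
        alt_aa <- aa[[alt_cod]]
        if (alt_aa == "*") next
        syn <- alt_aa == aa[[codons[i]]]
        if ((ty == "s") == syn) {
          codons[i] <- alt_cod
          break
        }
      }
    }
    codons
  }

  with_seed(seed, {
    n_syn <- stats::rpois(2L, target_dS * S / 2)
    n_nonsyn <- stats::rpois(2L, target_dN * N / 2)
    a <- mutate_lineage(codons, n_syn[1L], n_nonsyn[1L])
    b <- mutate_lineage(codons, n_syn[2L], n_nonsyn[2L])
    list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""))
  })
}
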